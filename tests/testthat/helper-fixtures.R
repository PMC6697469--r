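## shared fixtures and oracles, built in code at test time

## a small complete synthetic experiment reused across tests
tiny_params <- function(seed = 42, ...) {
  sim_params(n_proteins = 60, n_complexes = 10, seed = seed, ...)
}

## run the feature -> score -> calibrate chain on a bundle
run_chain <- function(bundle, seed = 1, k_folds = 10,
                      target_precision = 0.5) {
  cleaned <- lapply(bundle$profiles, clean_profiles)
  peaks <- lapply(cleaned, fit_peaks)
  feats <- purrr::map2(cleaned, peaks, compute_pair_features)
  features <- combine_replicate_features(feats)
  features <- coexpression_feature(features, bundle$coexpression)
  labelled <- build_gold_labels(bundle$gold, features)
  fcols <- setdiff(names(labelled)[vapply(labelled, is.numeric, logical(1))],
                   "coexpression_imputed")
  scored <- score_pairs(labelled, feature_cols = fcols, k_folds = k_folds,
                        seed = seed)
  calib <- calibrate_interaction_scores(scored)
  net <- suppressMessages(threshold_network(calib, target_precision))
  list(features = features, calib = calib, net = net)
}

## truth-measured FDR of a thresholded network
truth_fdr <- function(net, truth) {
  tp <- true_pairs(truth)
  1 - nrow(dplyr::semi_join(net$edges, tp,
                            by = c("protein_a", "protein_b"))) /
    nrow(net$edges)
}

## tibble of edges from a plain pair list with unit/other weights
edge_tbl <- function(a, b, w = 1) {
  tibble::tibble(protein_a = pmin(a, b), protein_b = pmax(a, b), weight = w)
}

## canonical toy graphs
k4_edges <- function() {
  ids <- c("A", "B", "C", "D")
  idx <- utils::combn(4, 2)
  edge_tbl(ids[idx[1, ]], ids[idx[2, ]])
}

bridged_triangles <- function(w = 1) {
  edge_tbl(c("A", "A", "B", "D", "D", "E", "C"),
           c("B", "C", "C", "E", "F", "F", "D"), w)
}

## cohesiveness of a vertex set on an edge table (independent of the
## implementation's incremental bookkeeping)
cohesiveness_of <- function(edges, V, p) {
  w_in <- sum(edges$weight[edges$protein_a %in% V & edges$protein_b %in% V])
  w_bound <- sum(edges$weight[xor(edges$protein_a %in% V,
                                  edges$protein_b %in% V)])
  w_in / (w_in + w_bound + p * length(V))
}

## brute-force maximum-weight one-to-one assignment by permutation search
brute_force_assignment <- function(om) {
  nr <- nrow(om)
  nc <- ncol(om)
  if (nr <= nc) {
    perms <- all_k_permutations(nc, nr)
    best <- -Inf
    for (i in seq_len(nrow(perms))) {
      s <- sum(om[cbind(seq_len(nr), perms[i, ])])
      if (s > best) best <- s
    }
  } else {
    best <- brute_force_assignment(t(om))
  }
  best
}

## all ordered selections of k items from 1..n (n!/(n-k)! rows)
all_k_permutations <- function(n, k) {
  if (k == 0) return(matrix(integer(0), nrow = 1, ncol = 0))
  out <- NULL
  for (i in seq_len(n)) {
    sub <- all_k_permutations(n, k - 1)
    sub <- sub[apply(sub, 1, function(r) !(i %in% r)), , drop = FALSE]
    out <- rbind(out, cbind(i, sub))
  }
  out
}

## exact upper-tail hypergeometric P(X >= k) by enumerating all subsets
enum_hyper_p <- function(N, K, n, k) {
  subsets <- utils::combn(N, n)
  annotated <- seq_len(K)   # wlog the first K universe members are annotated
  hits <- apply(subsets, 2, function(s) sum(s %in% annotated) >= k)
  mean(hits)
}
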