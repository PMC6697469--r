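#' Clustering parameters for two-stage complex detection
#'
#' Defaults follow the optimum reported for a 54-fraction SEC-PCP membrane
#' interactome (`p = 5000`, `dens = 0.001`, `inflation = 20`,
#' `min_score = 0.50`) with the rescue pass re-clustering unclustered pairs
#' scoring above 0.75.
#'
#' @param p ClusterONE penalty modelling unobserved interactions (>= 0).
#' @param dens minimum complex density in `[0, 1]`.
#' @param inflation MCL inflation (> 1); larger values give finer clusters.
#' @param min_score minimum interaction score of edges entering clustering.
#' @param rescue_score score threshold for the second (rescue) pass.
#' @param overlap_merge ClusterONE candidate clusters with pairwise overlap
#'   score at least this are merged (default 0.8, the algorithm's published
#'   default).
#' @param min_size minimum complex size (default 3).
#' @return a `clustering_params` list.
#' @export
clustering_params <- function(p = 5000, dens = 0.001, inflation = 20,
                              min_score = 0.5, rescue_score = 0.75,
                              overlap_merge = 0.8, min_size = 3L) {
  stopifnot(p >= 0, dens >= 0, dens <= 1, inflation > 1,
            min_score >= 0, min_score <= 1,
            rescue_score >= 0, rescue_score <= 1,
            overlap_merge > 0, min_size >= 1)
  structure(list(p = p, dens = dens, inflation = inflation,
                 min_score = min_score, rescue_score = rescue_score,
                 overlap_merge = overlap_merge,
                 min_size = as.integer(min_size)),
            class = "clustering_params")
}

edge_weight_col <- function(edges) {
  for (cand in c("weight", "interaction_score", "score")) {
    if (cand %in% names(edges)) return(cand)
  }
  stop("edge table needs a weight/interaction_score column", call. = FALSE)
}

edges_to_adjacency <- function(edges) {
  wcol <- edge_weight_col(edges)
  nodes <- sort(unique(c(edges$protein_a, edges$protein_b)))
  W <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  ia <- match(edges$protein_a, nodes)
  ib <- match(edges$protein_b, nodes)
  W[cbind(ia, ib)] <- edges[[wcol]]
  W[cbind(ib, ia)] <- edges[[wcol]]
  W
}

## overlap score between two protein sets: |A n B|^2 / (|A| |B|)
overlap_score <- function(a, b) {
  length(intersect(a, b))^2 / (length(a) * length(b))
}

#' Greedy cohesive clustering (ClusterONE-style)
#'
#' Grows candidate clusters from high-degree seeds by greedily maximising
#' the cohesiveness f(V) = w_in / (w_in + w_bound + p * |V|), where w_in is
#' the total edge weight inside V and w_bound the total weight crossing its
#' boundary. From each seed, the single vertex addition or removal that most
#' improves f is applied until no move improves it. Candidate clusters with
#' pairwise overlap score at least `overlap_merge` are merged (transitively);
#' clusters smaller than `min_size` or with weighted density below `dens`
#' are discarded. Deterministic: seeds are visited in decreasing weighted
#' degree (ties by node id), and tied moves prefer the lowest node index.
#'
#' @param edges tibble `protein_a`, `protein_b` plus a `weight` /
#'   `interaction_score` column with values in `[0, 1]`.
#' @param p cohesiveness penalty (models unobserved interactions).
#' @param dens minimum weighted density, 2 w_in / (|V| (|V|-1)).
#' @param overlap_merge merge threshold on the overlap score.
#' @param min_size minimum cluster size.
#' @return list of character vectors (clusters, members sorted).
#' @export
cluster_one <- function(edges, p = 2, dens = 0, overlap_merge = 0.8,
                        min_size = 3L) {
  if (is.null(edges) || !nrow(edges)) return(list())
  W <- edges_to_adjacency(edges)
  n <- nrow(W)
  deg <- rowSums(W)
  seed_order <- order(-deg, rownames(W))
  assigned <- rep(FALSE, n)
  clusters <- list()
  for (s in seed_order) {
    if (assigned[s]) next
    V <- s
    w_in <- 0
    repeat {
      conn <- colSums(W[V, , drop = FALSE])   # weight of each vertex to V
      w_bound <- sum(conn[-V])
      f0 <- cohesiveness(w_in, w_bound, p, length(V))
      ## additions
      cand_add <- setdiff(which(conn > 0), V)
      f_add <- if (length(cand_add)) {
        vapply(cand_add, function(v) {
          cohesiveness(w_in + conn[v],
                       w_bound - conn[v] + (deg[v] - conn[v]),
                       p, length(V) + 1)
        }, numeric(1))
      } else numeric(0)
      ## removals (never empty the cluster)
      cand_rm <- if (length(V) > 1) V else integer(0)
      f_rm <- if (length(cand_rm)) {
        vapply(cand_rm, function(v) {
          cin <- conn[v]                       # weight of v into V (v in V)
          cohesiveness(w_in - cin,
                       w_bound - (deg[v] - cin) + cin,
                       p, length(V) - 1)
        }, numeric(1))
      } else numeric(0)
      moves <- c(f_add, f_rm)
      if (!length(moves) || max(moves) <= f0 + 1e-12) break
      best <- which.max(moves)
      if (best <= length(cand_add)) {
        v <- cand_add[best]
        w_in <- w_in + conn[v]
        V <- c(V, v)
      } else {
        v <- cand_rm[best - length(cand_add)]
        w_in <- w_in - conn[v]
        V <- setdiff(V, v)
      }
    }
    assigned[V] <- TRUE
    clusters <- c(clusters, list(sort(rownames(W)[V])))
  }
  ## merge highly overlapping candidates (transitive closure)
  if (length(clusters) > 1 && is.finite(overlap_merge)) {
    repeat {
      k <- length(clusters)
      om <- matrix(0, k, k)
      for (i in seq_len(k - 1)) for (j in (i + 1):k) {
        om[i, j] <- overlap_score(clusters[[i]], clusters[[j]])
      }
      hit <- which(om >= overlap_merge, arr.ind = TRUE)
      if (!nrow(hit)) break
      i <- hit[1, 1]; j <- hit[1, 2]
      clusters[[i]] <- sort(union(clusters[[i]], clusters[[j]]))
      clusters[[j]] <- NULL
    }
  }
  clusters <- unique(clusters)
  ## size and density filters
  keep <- vapply(clusters, function(cl) {
    if (length(cl) < min_size) return(FALSE)
    idx <- match(cl, rownames(W))
    w_in <- sum(W[idx, idx]) / 2
    d <- 2 * w_in / (length(cl) * (length(cl) - 1))
    d >= dens
  }, logical(1))
  clusters[keep]
}

cohesiveness <- function(w_in, w_bound, p, size) {
  den <- w_in + w_bound + p * size
  if (den <= 0) return(0)
  w_in / den
}

#' Markov clustering (MCL)
#'
#' Builds a column-stochastic transition matrix (with self-loops weighted by
#' each node's maximum incident edge weight), then alternates expansion
#' (matrix squaring) and inflation (elementwise power `inflation`, column
#' renormalisation) until the matrix changes by less than `tol` or
#' `max_iter` is reached. Clusters are the connected components of the
#' non-negligible entries of the limit matrix. Columns are verified to stay
#' stochastic to within 1e-9 after every inflation; the attribute
#' `column_sum_dev` records the worst deviation and `converged` whether the
#' iteration reached `tol`.
#'
#' @param edges tibble `protein_a`, `protein_b` plus a weight column.
#' @param inflation inflation exponent (> 1).
#' @param max_iter,tol iteration controls.
#' @return list of character vectors (disjoint clusters) with attributes
#'   `converged` and `column_sum_dev`.
#' @export
mcl <- function(edges, inflation = 2, max_iter = 100, tol = 1e-6) {
  stopifnot(inflation > 1)
  if (is.null(edges) || !nrow(edges)) return(structure(list(),
                                                       converged = TRUE,
                                                       column_sum_dev = 0))
  W <- edges_to_adjacency(edges)
  selfw <- apply(W, 1, max)
  selfw[selfw <= 0] <- 1
  diag(W) <- selfw
  M <- sweep(W, 2, colSums(W), "/")
  dev <- 0
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    M2 <- M %*% M
    M2 <- M2^inflation
    M2[M2 < 1e-300] <- 0
    cs <- colSums(M2)
    cs[cs == 0] <- 1
    M2 <- sweep(M2, 2, cs, "/")
    dev <- max(dev, max(abs(colSums(M2) - 1)))
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  keep <- (M + t(M)) > 1e-8
  g <- igraph::graph_from_adjacency_matrix(keep, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  clusters <- split(rownames(W), comp)
  clusters <- unname(lapply(clusters, sort))
  structure(clusters[order(vapply(clusters, `[`, character(1), 1))],
            converged = converged, column_sum_dev = dev)
}

#' Two-stage complex detection with rescue of high-scoring pairs
#'
#' Thresholds the network at `min_score`, runs ClusterONE, refines each
#' candidate cluster's induced subgraph with MCL, and keeps refined clusters
#' of at least `min_size` members. Pairs of the input network that do not
#' co-occur inside any resulting complex but score above `rescue_score` form
#' a rescue network, on which the two-stage procedure is re-run; the final
#' complex set is the de-duplicated union, each complex recording which pass
#' produced it.
#'
#' @param edges tibble `protein_a`, `protein_b` plus an
#'   `interaction_score` / `weight` column.
#' @param params a [clustering_params()] object.
#' @return object of class `pcp_complexes`: tibble `complex`, `provenance`
#'   (`"primary"` or `"rescue"`), `size`, `members` (list column of sorted
#'   ids), with the parameters in attribute `params`.
#' @export
two_stage_cluster <- function(edges, params = clustering_params()) {
  stopifnot(inherits(params, "clustering_params"))
  wcol <- edge_weight_col(edges)
  net <- filter(edges, .data[[wcol]] >= params$min_score)
  pass <- function(e) {
    cands <- cluster_one(e, p = params$p, dens = params$dens,
                         overlap_merge = params$overlap_merge,
                         min_size = params$min_size)
    out <- list()
    for (cl in cands) {
      sub <- filter(e, .data$protein_a %in% cl & .data$protein_b %in% cl)
      fine <- mcl(sub, inflation = params$inflation)
      fine <- fine[vapply(fine, length, integer(1)) >= params$min_size]
      out <- c(out, fine)
    }
    unique(out)
  }
  primary <- pass(net)
  inside <- purrr::map_dfr(primary, all_pairs)
  clustered_key <- if (nrow(inside)) {
    pair_key(inside$protein_a, inside$protein_b)
  } else character(0)
  rescue_net <- filter(edges, .data[[wcol]] > params$rescue_score,
                       !pair_key(.data$protein_a, .data$protein_b) %in%
                         clustered_key)
  rescue <- pass(rescue_net)
  members <- c(primary, rescue)
  provenance <- rep(c("primary", "rescue"),
                    c(length(primary), length(rescue)))
  dup <- duplicated(vapply(members, paste, character(1), collapse = ";"))
  members <- members[!dup]
  provenance <- provenance[!dup]
  out <- tibble(
    complex = sprintf("K%03d", seq_along(members)),
    provenance = provenance,
    size = vapply(members, length, integer(1)),
    members = members)
  attr(out, "params") <- params
  structure(out, class = c("pcp_complexes", class(out)))
}

complex_members <- function(x) {
  if (inherits(x, "pcp_complexes")) return(x$members)
  if (inherits(x, "pcp_gold")) return(unname(gold_complex_list(x)))
  if (is.list(x) && !is.data.frame(x)) return(unname(x))
  stop("cannot interpret complex set of class ", class(x)[1], call. = FALSE)
}

#' Maximum matching ratio between predicted and reference complexes
#'
#' Computes the overlap score w = |A n B|^2 / (|A| |B|) for every
#' (predicted, reference) pair and finds the exact maximum-weight one-to-one
#' assignment on that bipartite matrix. The maximum matching ratio (MMR) is
#' the sum of matched overlap scores divided by the number of reference
#' complexes.
#'
#' @param predicted,reference complex sets: `pcp_complexes`, `pcp_gold`, or
#'   plain lists of member vectors.
#' @return object of class `pcp_match`: list with `mmr`, `matches` (tibble
#'   `predicted`, `reference`, `omega`), and `omega` (the full matrix).
#' @export
matching_ratio <- function(predicted, reference) {
  pl <- complex_members(predicted)
  rl <- complex_members(reference)
  if (!length(pl) || !length(rl)) {
    return(structure(list(mmr = 0,
                          matches = tibble(predicted = integer(),
                                           reference = integer(),
                                           omega = double()),
                          omega = matrix(0, length(pl), length(rl))),
                     class = "pcp_match"))
  }
  om <- matrix(0, length(pl), length(rl))
  for (i in seq_along(pl)) for (j in seq_along(rl)) {
    om[i, j] <- overlap_score(pl[[i]], rl[[j]])
  }
  matches <- max_weight_assignment(om)
  mmr <- sum(matches$omega) / length(rl)
  structure(list(mmr = mmr, matches = matches, omega = om),
            class = "pcp_match")
}

## exact maximum-weight one-to-one assignment on a (possibly rectangular)
## non-negative matrix, via igraph's weighted bipartite matching
max_weight_assignment <- function(om) {
  hit <- which(om > 0, arr.ind = TRUE)
  if (!nrow(hit)) {
    return(tibble(predicted = integer(), reference = integer(),
                  omega = double()))
  }
  nl <- nrow(om)
  edges_df <- data.frame(from = paste0("L", hit[, 1]),
                         to = paste0("R", hit[, 2]),
                         weight = om[hit])
  g <- igraph::graph_from_data_frame(edges_df, directed = FALSE)
  igraph::V(g)$type <- startsWith(igraph::V(g)$name, "R")
  mm <- igraph::max_bipartite_match(g, types = igraph::V(g)$type,
                                    weights = igraph::E(g)$weight)
  mt <- mm$matching
  left <- names(mt)[startsWith(names(mt), "L") & !is.na(mt)]
  tibble(
    predicted = as.integer(sub("^L", "", left)),
    reference = as.integer(sub("^R", "", mt[left]))
  ) %>%
    mutate(omega = om[cbind(.data$predicted, .data$reference)]) %>%
    arrange(.data$predicted)
}

#' @export
print.pcp_match <- function(x, ...) {
  cat("<pcp_match> MMR = ", round(x$mmr, 4), " (", nrow(x$matches),
      " matched of ", ncol(x$omega), " reference complexes)\n", sep = "")
  invisible(x)
}

#' Grid search over clustering parameters, maximising the MMR
#'
#' Evaluates [two_stage_cluster()] at every point of the parameter grid and
#' returns the point maximising the maximum matching ratio against the
#' reference complexes (ties resolved by grid order).
#'
#' @param edges scored edge table.
#' @param reference gold-standard complexes (any form accepted by
#'   [matching_ratio()]).
#' @param grid named list of parameter vectors (`p`, `dens`, `inflation`,
#'   `min_score`; anything omitted keeps the [clustering_params()] default).
#'   The default grid brackets the reported optimum.
#' @param rescue_score,overlap_merge,min_size fixed non-grid parameters.
#' @return list with `best_params` (a [clustering_params()]), `best_mmr`,
#'   and `table` (tibble of every grid point and its MMR).
#' @export
grid_search_params <- function(edges, reference,
                               grid = list(p = c(0, 2, 50, 500, 5000),
                                           dens = c(0.001, 0.1, 0.3),
                                           inflation = c(2, 4, 10, 20),
                                           min_score = c(0.5, 0.75)),
                               rescue_score = 0.75, overlap_merge = 0.8,
                               min_size = 3L) {
  stopifnot(length(grid) > 0, all(lengths(grid) > 0))
  defaults <- list(p = 5000, dens = 0.001, inflation = 20, min_score = 0.5)
  grid <- modifyList(defaults, grid[intersect(names(grid), names(defaults))])
  pts <- do.call(tidyr::expand_grid, grid)
  mmrs <- purrr::pmap_dbl(pts, function(p, dens, inflation, min_score) {
    cp <- clustering_params(p = p, dens = dens, inflation = inflation,
                            min_score = min_score,
                            rescue_score = rescue_score,
                            overlap_merge = overlap_merge,
                            min_size = min_size)
    matching_ratio(two_stage_cluster(edges, cp), reference)$mmr
  })
  tab <- mutate(pts, mmr = mmrs)
  best <- which.max(mmrs)
  list(
    best_params = clustering_params(
      p = pts$p[best], dens = pts$dens[best],
      inflation = pts$inflation[best], min_score = pts$min_score[best],
      rescue_score = rescue_score, overlap_merge = overlap_merge,
      min_size = min_size),
    best_mmr = mmrs[best],
    table = tab)
}
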