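#' Filter an annotation map to active terms
#'
#' Keeps terms annotating strictly more than `min_count` and strictly fewer
#' than `max_count` proteins (exclusive bounds, defaults 20 and 1000). Every
#' fraction / enrichment computation applies this filter first.
#'
#' @param annotations tibble `protein`, `term`.
#' @param min_count,max_count exclusive term-size bounds.
#' @return filtered tibble.
#' @export
filter_terms <- function(annotations, min_count = 20, max_count = 1000) {
  sizes <- count(distinct(annotations, .data$protein, .data$term),
                 .data$term, name = "n_annotated")
  active <- sizes$term[sizes$n_annotated > min_count &
                         sizes$n_annotated < max_count]
  filter(annotations, .data$term %in% active)
}

network_edges <- function(network) {
  if (inherits(network, "pcp_interactome")) return(network$edges)
  stopifnot(is.data.frame(network),
            all(c("protein_a", "protein_b") %in% names(network)))
  network
}

#' Fraction of network pairs sharing at least one active annotation term
#'
#' Pairs with an unannotated member count in the denominator (they cannot
#' share a term); this denominator policy is deliberate and matches the
#' "fraction of all predicted pairs" reading.
#'
#' @param network edge tibble or `pcp_interactome`.
#' @param annotations tibble `protein`, `term`.
#' @param min_count,max_count active-term filter bounds (set to `-Inf` /
#'   `Inf` to disable).
#' @return a single fraction in `[0, 1]`.
#' @export
shared_annotation_fraction <- function(network, annotations,
                                       min_count = 20, max_count = 1000) {
  edges <- network_edges(network)
  if (!nrow(edges)) stop("empty network", call. = FALSE)
  ann <- filter_terms(annotations, min_count, max_count)
  term_sets <- split(ann$term, ann$protein)
  ta <- term_sets[edges$protein_a]
  tb <- term_sets[edges$protein_b]
  shared <- purrr::map2_lgl(ta, tb, function(u, v) {
    if (is.null(u) || is.null(v)) return(FALSE)
    any(u %in% v)
  })
  mean(shared)
}

#' Fraction of covered network pairs with positively correlated phenotypes
#'
#' Strictly positive Pearson correlation (`R > 0`) between the two members'
#' phenotype vectors; pairs with a member absent from the phenotype matrix
#' are excluded from numerator and denominator (their count is reported in
#' the `n_uncovered` attribute).
#'
#' @param network edge tibble or `pcp_interactome`.
#' @param phenotypes tibble `protein` + condition columns (at least 3
#'   conditions).
#' @return fraction in `[0, 1]` with attributes `n_covered`, `n_uncovered`.
#' @export
phenotype_positive_fraction <- function(network, phenotypes) {
  edges <- network_edges(network)
  if (!nrow(edges)) stop("empty network", call. = FALSE)
  pm <- profile_matrix_values(phenotypes)
  if (ncol(pm) < 3) stop("need at least 3 phenotype conditions",
                         call. = FALSE)
  ia <- match(edges$protein_a, rownames(pm))
  ib <- match(edges$protein_b, rownames(pm))
  covered <- !is.na(ia) & !is.na(ib)
  if (!any(covered)) stop("no network pair covered by the phenotype matrix",
                          call. = FALSE)
  cm <- suppressWarnings(cor(t(pm)))
  r <- cm[cbind(ia[covered], ib[covered])]
  structure(mean(r > 0, na.rm = TRUE),
            n_covered = sum(covered), n_uncovered = sum(!covered))
}

validation_report <- function(metric, observed, null_values, params = list()) {
  null_sd <- sd(null_values)
  z <- if (isTRUE(null_sd > 0)) (observed - mean(null_values)) / null_sd
       else NA_real_
  p <- (1 + sum(null_values >= observed)) / (1 + length(null_values))
  structure(
    tibble(metric = metric, observed = observed,
           null_mean = mean(null_values), null_sd = null_sd,
           n_null = length(null_values), z = z, p_empirical = p),
    null_values = null_values, params = params,
    class = c("pcp_validation", "tbl_df", "tbl", "data.frame"))
}

#' Rewired-network null model for a network-level metric
#'
#' Each null network keeps the observed protein set and edge count but
#' redraws the edges as uniformly random unique pairs (not
#' degree-preserving — the null is defined constructively this way). The
#' metric is evaluated on the observed and on every null network; the
#' report carries the null mean and sd, a z-score, and an add-one-smoothed
#' empirical upper-tail p-value, which is therefore never exactly 0.
#'
#' @param network edge tibble or `pcp_interactome`.
#' @param metric function taking an edge tibble and returning one number.
#' @param n_iter number of null networks (default 1000).
#' @param seed RNG seed.
#' @param metric_name label stored in the report.
#' @param nodes protein set over which null edges are drawn; defaults to
#'   the proteins participating in the network.
#' @return a `pcp_validation` tibble (one row); the null sample is kept in
#'   attribute `null_values`.
#' @export
rewired_null <- function(network, metric, n_iter = 1000, seed = 1L,
                         metric_name = "metric", nodes = NULL) {
  edges <- network_edges(network)
  nodes <- nodes %||% sort(unique(c(edges$protein_a, edges$protein_b)))
  m <- nrow(edges)
  universe <- all_pairs(nodes)
  if (m > nrow(universe)) {
    stop("edge count exceeds the number of possible pairs", call. = FALSE)
  }
  observed <- metric(edges)
  nulls <- with_rng(seed, vapply(seq_len(n_iter), function(i) {
    metric(universe[sample(nrow(universe), m), ])
  }, numeric(1)))
  validation_report(metric_name, observed, nulls,
                    params = list(n_iter = n_iter, seed = seed,
                                  n_nodes = length(nodes), n_edges = m))
}

#' Edge overlap between two networks
#'
#' @param net_a,net_b edge tibbles (canonical pair order) or
#'   `pcp_interactome` objects.
#' @return number of shared edges.
#' @export
network_overlap <- function(net_a, net_b) {
  a <- network_edges(net_a)
  b <- network_edges(net_b)
  nrow(semi_join(a, b, by = c("protein_a", "protein_b")))
}

#' Permutation p-value for the overlap of two networks
#'
#' Redraws `net_a` as random unique pairs over its own protein set and
#' counts the overlap with `net_b`; p = (1 + #{null >= observed}) /
#' (1 + n_iter).
#'
#' @inheritParams network_overlap
#' @param n_iter permutations (default 1000).
#' @param seed RNG seed.
#' @param nodes protein set over which null edges are drawn; defaults to
#'   the proteins of `net_a`.
#' @return a `pcp_validation` tibble (metric `"overlap"`).
#' @export
overlap_permutation_p <- function(net_a, net_b, n_iter = 1000, seed = 1L,
                                  nodes = NULL) {
  b <- network_edges(net_b)
  rewired_null(net_a,
               metric = function(e) network_overlap(e, b),
               n_iter = n_iter, seed = seed, metric_name = "overlap",
               nodes = nodes)
}

#' High-confidence subset: interactions present in every validating network
#'
#' @param predicted edge tibble or `pcp_interactome`.
#' @param validating list of edge tibbles (at least one).
#' @return tibble of edges present in the predicted network and in every
#'   validating network (order of the validating list is irrelevant).
#' @export
high_confidence <- function(predicted, validating) {
  stopifnot(length(validating) >= 1)
  out <- network_edges(predicted)
  for (v in validating) {
    out <- semi_join(out, network_edges(v), by = c("protein_a", "protein_b"))
  }
  out
}

## vectorised per-(complex, term) hypergeometric enrichment machinery
enrichment_counts <- function(member_list, ann, universe) {
  terms <- sort(unique(ann$term))
  A <- matrix(0L, length(universe), length(terms),
              dimnames = list(universe, terms))
  ann_u <- ann[ann$protein %in% universe, ]
  A[cbind(match(ann_u$protein, universe), match(ann_u$term, terms))] <- 1L
  C <- matrix(0L, length(member_list), length(universe))
  for (i in seq_along(member_list)) {
    C[i, match(intersect(member_list[[i]], universe), universe)] <- 1L
  }
  list(k = C %*% A,                      # annotated members per (complex, term)
       K = colSums(A),                   # annotated proteins per term
       n = rowSums(C),                   # complex size within universe
       terms = terms)
}

#' Per-complex annotation enrichment (hypergeometric + BH)
#'
#' For every (complex, active term) combination, computes the upper-tail
#' hypergeometric probability of drawing at least the observed number of
#' annotated members, given the term's annotation count in the universe.
#' Benjamini-Hochberg correction is applied jointly across all
#' (complex, term) tests; a complex is enriched when any corrected p-value
#' is below `alpha`.
#'
#' @param complexes a `pcp_complexes`, `pcp_gold`, or list of member
#'   vectors.
#' @param annotations tibble `protein`, `term`.
#' @param alpha significance level on BH-adjusted p-values.
#' @param universe protein universe for the test; default is the union of
#'   all complex members.
#' @param min_count,max_count active-term filter bounds.
#' @return list with `tests` (tibble `complex`, `term`, `k`, `K`, `n`, `N`,
#'   `p`, `p_adj`), `n_enriched`, and `enriched` (complex indices).
#' @export
complex_enrichment <- function(complexes, annotations, alpha = 0.05,
                               universe = NULL, min_count = 20,
                               max_count = 1000) {
  members <- complex_members(complexes)
  universe <- universe %||% sort(unique(unlist(members)))
  ann <- filter_terms(distinct(annotations, .data$protein, .data$term),
                      min_count, max_count)
  ann <- ann[ann$protein %in% universe, ]
  if (!nrow(ann) || !length(members)) {
    return(list(tests = tibble(complex = integer(), term = character(),
                               k = integer(), K = integer(), n = integer(),
                               N = integer(), p = double(), p_adj = double()),
                n_enriched = 0L, enriched = integer()))
  }
  ec <- enrichment_counts(members, ann, universe)
  N <- length(universe)
  tests <- tidyr::expand_grid(complex = seq_along(members),
                              term_idx = seq_along(ec$terms)) %>%
    mutate(term = ec$terms[.data$term_idx],
           k = as.integer(ec$k[cbind(.data$complex, .data$term_idx)]),
           K = as.integer(ec$K[.data$term_idx]),
           n = as.integer(ec$n[.data$complex]),
           N = N,
           p = phyper(.data$k - 1, .data$K, N - .data$K, .data$n,
                      lower.tail = FALSE)) %>%
    select(-"term_idx") %>%
    mutate(p_adj = p.adjust(.data$p, method = "BH"))
  enriched <- sort(unique(tests$complex[tests$p_adj < alpha]))
  list(tests = tests, n_enriched = length(enriched), enriched = enriched)
}

#' Random-complex null for the enriched-complex count
#'
#' Each null complex set preserves the observed size multiset; members are
#' drawn uniformly without replacement from the universe, complex by
#' complex. The enriched-complex count (same test and BH policy as
#' [complex_enrichment()]) is evaluated per null set.
#'
#' @inheritParams complex_enrichment
#' @param n_iter null sets (default 1000).
#' @param seed RNG seed.
#' @return a `pcp_validation` tibble (metric `"n_enriched_complexes"`).
#' @export
random_complex_null <- function(complexes, annotations, universe = NULL,
                                n_iter = 1000, seed = 1L, alpha = 0.05,
                                min_count = 20, max_count = 1000) {
  members <- complex_members(complexes)
  universe <- universe %||% sort(unique(unlist(members)))
  stopifnot(all(unlist(members) %in% universe))
  sizes <- vapply(members, length, integer(1))
  count_enriched <- function(mm) {
    complex_enrichment(mm, annotations, alpha = alpha, universe = universe,
                       min_count = min_count,
                       max_count = max_count)$n_enriched
  }
  observed <- count_enriched(members)
  nulls <- with_rng(seed, vapply(seq_len(n_iter), function(i) {
    count_enriched(lapply(sizes, function(s) sample(universe, s)))
  }, numeric(1)))
  validation_report("n_enriched_complexes", observed, nulls,
                    params = list(n_iter = n_iter, seed = seed,
                                  alpha = alpha, sizes = sizes))
}

#' Wilcoxon rank-sum test with midranks
#'
#' The statistic is the sum of midranks of the first sample in the pooled
#' ranking. When both samples have at most `exact_max` observations the
#' p-value is exact, by full enumeration of all assignments of pooled
#' midranks to the first sample (ties handled by midranks throughout);
#' otherwise a normal approximation with tie correction and continuity
#' correction is used.
#'
#' @param a,b numeric samples (non-empty).
#' @param alternative `"two.sided"` (default), `"greater"`, or `"less"`,
#'   with respect to sample `a`.
#' @param exact_max maximum per-sample size for exact enumeration.
#' @return tibble `statistic` (rank sum of `a`), `p_value`, `method`.
#' @export
rank_sum_test <- function(a, b, alternative = c("two.sided", "greater",
                                                "less"), exact_max = 10) {
  alternative <- match.arg(alternative)
  stopifnot(length(a) > 0, length(b) > 0)
  n1 <- length(a)
  n2 <- length(b)
  ranks <- rank(c(a, b))
  w <- sum(ranks[seq_len(n1)])
  if (n1 <= exact_max && n2 <= exact_max) {
    sets <- combn(n1 + n2, n1)
    sums <- colSums(matrix(ranks[sets], nrow = n1))
    tol <- 1e-9
    p_le <- mean(sums <= w + tol)
    p_ge <- mean(sums >= w - tol)
    p <- switch(alternative,
                two.sided = min(1, 2 * min(p_le, p_ge)),
                greater = p_ge,
                less = p_le)
    method <- "exact enumeration (midranks)"
  } else {
    N <- n1 + n2
    tie_tab <- table(ranks)
    tie_term <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
    mu <- n1 * (N + 1) / 2
    sigma <- sqrt(n1 * n2 / 12 * ((N + 1) - tie_term))
    cc <- 0.5
    z_g <- (w - mu - cc) / sigma
    z_l <- (w - mu + cc) / sigma
    p <- switch(alternative,
                two.sided = min(1, 2 * min(pnorm(z_l),
                                           pnorm(z_g, lower.tail = FALSE))),
                greater = pnorm(z_g, lower.tail = FALSE),
                less = pnorm(z_l))
    method <- "normal approximation with tie correction"
  }
  tibble(statistic = w, p_value = p, method = method)
}

#' Gene-ontology vocabulary for cell-envelope association
#'
#' The standard list of cellular-component terms used to call a bacterial
#' protein cell-envelope associated (membrane, cell wall, and periplasm
#' compartments).
#'
#' @return character vector of term names.
#' @export
cell_envelope_terms <- function() {
  c("Anchored component of membrane",
    "Anchored component of external side of membrane",
    "Anchored component of periplasmic side of outer membrane",
    "Extrinsic component of periplasmic side of plasma membrane",
    "Gram-negative bacterium cell wall",
    "Extrinsic component of plasma membrane",
    "Integral component of membrane",
    "Cell envelope",
    "Cell outer membrane",
    "Integral component of cell outer membrane",
    "Integral component of plasma membrane",
    "Membrane",
    "Cell wall",
    "External side of cell outer membrane",
    "Intrinsic component of cell outer membrane",
    "Intrinsic component of membrane",
    "Intrinsic component of plasma membrane",
    "Plasma membrane",
    "Extrinsic component of cell outer membrane",
    "Extrinsic component of membrane",
    "Intrinsic component of external side of plasma membrane",
    "Intrinsic component of periplasmic side of plasma membrane",
    "Intrinsic component of periplasmic side of cell outer membrane",
    "Outer-membrane bounded periplasmic space",
    "Periplasmic space",
    "Intrinsic component of cytoplasmic side of plasma membrane",
    "Outer membrane",
    "Periplasmic side of outer membrane",
    "Peptidoglycan-based cell wall")
}

#' Classify proteins as cell-envelope associated
#'
#' A protein is flagged when annotated with at least one term of the
#' envelope vocabulary (case-insensitive match). Proteins present in the
#' annotation map but carrying none of the listed terms are `FALSE`.
#'
#' @param annotations tibble `protein`, `term`.
#' @param envelope_terms term vocabulary (default [cell_envelope_terms()]).
#' @return tibble `protein`, `cell_envelope` (logical), with attribute
#'   `counts` = c(envelope, total).
#' @export
classify_cell_envelope <- function(annotations,
                                   envelope_terms = cell_envelope_terms()) {
  env <- tolower(envelope_terms)
  out <- annotations %>%
    group_by(.data$protein) %>%
    summarise(cell_envelope = any(tolower(.data$term) %in% env),
              .groups = "drop")
  structure(out, counts = c(envelope = sum(out$cell_envelope),
                            total = nrow(out)))
}
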