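toy_annotations <- function() {
  tibble::tibble(
    protein = c("A", "B", "C", "D", "E"),
    term = c("T1", "T1", "T2", "T2", "T3"))
}

test_that("shared-annotation fractions count unannotated pairs in the
           denominator", {
  net <- tibble::tibble(protein_a = c("A", "C"), protein_b = c("B", "E"))
  ## A,B share T1; C (T2) and E (T3) do not
  expect_equal(shared_annotation_fraction(net, toy_annotations(),
                                          min_count = -Inf,
                                          max_count = Inf), 0.5)
  one_term <- tibble::tibble(protein = c("A", "B", "C", "E"), term = "T")
  expect_equal(shared_annotation_fraction(net, one_term, min_count = -Inf,
                                          max_count = Inf), 1)
  expect_error(shared_annotation_fraction(net[0, ], toy_annotations()),
               "empty network")
})

test_that("the active-term filter applies exclusive size bounds", {
  ann <- dplyr::bind_rows(
    tibble::tibble(protein = sprintf("P%02d", 1:20), term = "small"),
    tibble::tibble(protein = sprintf("P%02d", 1:21), term = "ok"))
  kept <- filter_terms(ann, min_count = 20, max_count = 1000)
  expect_setequal(unique(kept$term), "ok")
})

test_that("shared fraction matches exhaustive enumeration on a random
           10-protein toy", {
  withr::local_seed(23)
  prot <- sprintf("P%02d", 1:10)
  ann <- tibble::tibble(protein = sample(prot, 18, replace = TRUE),
                        term = sample(c("T1", "T2", "T3"), 18,
                                      replace = TRUE)) %>%
    dplyr::distinct()
  pairs <- all_pairs(prot)
  got <- shared_annotation_fraction(pairs, ann, min_count = -Inf,
                                    max_count = Inf)
  oracle <- mean(apply(as.matrix(pairs), 1, function(pr) {
    ta <- ann$term[ann$protein == pr[1]]
    tb <- ann$term[ann$protein == pr[2]]
    length(intersect(ta, tb)) > 0
  }))
  expect_equal(got, oracle)
})

test_that("phenotype positivity is strict and covered-only", {
  ph <- tibble::tibble(protein = c("A", "B", "C", "D"),
                       cond_1 = c(1, 1, 1, 1), cond_2 = c(2, 2, 0, 3),
                       cond_3 = c(3, 3, 2, 2), cond_4 = c(4, 4, 1, 0))
  net <- tibble::tibble(protein_a = c("A", "A", "A"),
                        protein_b = c("B", "D", "Z"))
  f <- phenotype_positive_fraction(net, ph)
  ## A-B identical (R = 1 counts), A-D anticorrelated, A-Z uncovered
  expect_equal(as.numeric(f), 0.5)
  expect_equal(attr(f, "n_covered"), 2)
  expect_equal(attr(f, "n_uncovered"), 1)

  ## an exactly-zero correlation is not counted as positive
  ph0 <- tibble::tibble(protein = c("A", "B"),
                        cond_1 = c(-1, 1), cond_2 = c(0, 1),
                        cond_3 = c(1, 1), cond_4 = c(0, -3))
  stopifnot(abs(cor(c(-1, 0, 1, 0), c(1, 1, 1, -3))) < 1e-12)
  f0 <- phenotype_positive_fraction(
    tibble::tibble(protein_a = "A", protein_b = "B"), ph0)
  expect_equal(as.numeric(f0), 0)
})

test_that("rewired nulls match the full-enumeration oracle on a
           5-protein 3-edge toy", {
  prot <- c("A", "B", "C", "D", "E")
  net <- tibble::tibble(protein_a = c("A", "A", "B"),
                        protein_b = c("B", "C", "D"))
  ann <- toy_annotations()
  metric <- function(e) shared_annotation_fraction(e, ann,
                                                   min_count = -Inf,
                                                   max_count = Inf)
  rep <- rewired_null(net, metric, n_iter = 1500, seed = 3, nodes = prot)

  ## exact null mean by enumerating all choose(10, 3) edge sets
  universe <- all_pairs(prot)
  sets <- utils::combn(nrow(universe), 3, simplify = FALSE)
  exact <- vapply(sets, function(s) metric(universe[s, ]), numeric(1))
  mc_sd <- sd(exact) / sqrt(1500)
  expect_lt(abs(rep$null_mean - mean(exact)), 4 * mc_sd + 1e-9)
  expect_gt(rep$p_empirical, 0)
  expect_lte(rep$p_empirical, 1)
  ## z is consistent with its own null summary
  expect_equal(rep$z, (rep$observed - rep$null_mean) / rep$null_sd)
})

test_that("a constant metric yields an undefined z and p of 1", {
  net <- tibble::tibble(protein_a = c("A", "A"), protein_b = c("B", "C"))
  rep <- rewired_null(net, function(e) nrow(e), n_iter = 50, seed = 1)
  expect_true(is.na(rep$z))
  expect_equal(rep$p_empirical, 1)
})

test_that("requesting more edges than pairs exist is an error", {
  net <- tibble::tibble(protein_a = c("A", "A", "B"),
                        protein_b = c("B", "C", "C"))
  expect_error(rewired_null(dplyr::bind_rows(net, tibble::tibble(
    protein_a = "A", protein_b = "D")), nrow, n_iter = 5, seed = 1),
    NA)  # 4 edges over 4 proteins is fine
  big <- tibble::tibble(protein_a = rep("A", 3),
                        protein_b = c("B", "C", "D"))
  ## 3 proteins' worth of extra fake rows to exceed choose(n, 2)
  too_many <- dplyr::bind_rows(big, tibble::tibble(
    protein_a = c("B", "B", "C", "A"), protein_b = c("C", "D", "D", "B")))
  expect_error(rewired_null(too_many, nrow, n_iter = 5, seed = 1),
               "exceeds")
})

test_that("network overlap and its permutation p behave on identity and
           disjoint cases and match the closed-form expectation", {
  withr::local_seed(4)
  prot <- sprintf("P%02d", 1:30)
  uni <- all_pairs(prot)
  netA <- uni[sample(nrow(uni), 15), ]
  expect_equal(network_overlap(netA, netA), 15)
  ## a 15-edge network is essentially never reproduced by a random draw
  p_id <- overlap_permutation_p(netA, netA, n_iter = 200, seed = 2)
  expect_equal(p_id$p_empirical, 1 / 201)

  disjoint <- tibble::tibble(protein_a = "X", protein_b = "Y")
  expect_equal(network_overlap(netA, disjoint), 0)

  ## null mean of the overlap is m1 * m2 / choose(n, 2)
  a <- uni[sample(nrow(uni), 20), ]
  b <- uni[sample(nrow(uni), 20), ]
  rep <- overlap_permutation_p(a, b, n_iter = 2000, seed = 5,
                               nodes = prot)
  expected <- 20 * 20 / choose(30, 2)
  expect_lt(abs(rep$null_mean - expected),
            4 * rep$null_sd / sqrt(2000) + 1e-9)
})

test_that("the high-confidence set is the order-invariant intersection", {
  pred <- tibble::tibble(protein_a = c("A", "B", "C"),
                         protein_b = c("B", "C", "D"))
  v1 <- pred[1:2, ]
  v2 <- pred[2:3, ]
  expect_equal(high_confidence(pred, list(pred)), pred)
  expect_equal(nrow(high_confidence(pred, list(pred[0, ]))), 0)
  hc12 <- high_confidence(pred, list(v1, v2))
  hc21 <- high_confidence(pred, list(v2, v1))
  expect_equal(hc12, hc21)
  expect_equal(hc12, pred[2, ], ignore_attr = TRUE)
})

test_that("hypergeometric enrichment equals exhaustive enumeration on
           small universes and applies BH jointly", {
  ## the canonical worked example: universe 10, term of 4, complex of 3
  uni <- sprintf("U%02d", 1:10)
  ann <- tibble::tibble(protein = uni[1:4], term = "T")
  cx <- list(C1 = uni[1:3])
  enr <- complex_enrichment(cx, ann, universe = uni, min_count = -Inf,
                            max_count = Inf)
  expect_equal(enr$tests$p, 4 / 120, tolerance = 1e-12)
  expect_equal(enr$tests$p, enum_hyper_p(10, 4, 3, 3), tolerance = 1e-12)

  ## a term annotating the whole universe is never enriched
  ann_all <- tibble::tibble(protein = uni, term = "ALL")
  enr_all <- complex_enrichment(cx, ann_all, universe = uni,
                                min_count = -Inf, max_count = Inf)
  expect_equal(enr_all$tests$p, 1)

  ## random small cases against the enumeration oracle
  withr::local_seed(29)
  for (i in 1:5) {
    N <- sample(6:12, 1)
    K <- sample(2:(N - 1), 1)
    n <- sample(2:(N - 1), 1)
    u <- sprintf("U%02d", seq_len(N))
    a <- tibble::tibble(protein = u[seq_len(K)], term = "T")
    members <- sample(u, n)
    k_obs <- sum(members %in% u[seq_len(K)])
    enr_i <- complex_enrichment(list(members), a, universe = u,
                                min_count = -Inf, max_count = Inf)
    expect_equal(enr_i$tests$p, enum_hyper_p(N, K, n, k_obs),
                 tolerance = 1e-9)
  }

  ## BH adjustment equals the hand step-up procedure
  p <- enr$tests$p
  expect_equal(enr$tests$p_adj, p.adjust(p, "BH"))
  hand_bh <- function(p) {
    n <- length(p)
    o <- order(p)
    adj <- p[o] * n / seq_len(n)
    adj <- rev(cummin(rev(adj)))
    pmin(adj, 1)[order(o)]
  }
  ps <- c(0.01, 0.02, 0.04)
  expect_true(all(hand_bh(ps) < 0.05))
})

test_that("random-complex nulls preserve sizes and detect aligned
           annotations", {
  tr <- sim_truth(sim_params(n_proteins = 60, n_complexes = 8, seed = 15))
  maps <- sim_annotations(tr, n_terms = 20, term_size_range = c(6, 10),
                          co_complex_enrichment = 1)
  cx <- tr$complexes
  uni <- sprintf("P%04d", 1:60)
  rep <- random_complex_null(cx, maps$go, universe = uni, n_iter = 99,
                             seed = 6, min_count = 2, max_count = 59)
  ## strongly complex-aligned annotations: observed beats every null
  expect_equal(rep$p_empirical, 1 / 100)
  expect_gt(rep$z, 2)

  ## an unannotated universe can never enrich anything
  none <- random_complex_null(cx, maps$go[0, ], universe = uni,
                              n_iter = 20, seed = 7, min_count = -Inf,
                              max_count = Inf)
  expect_equal(none$observed, 0)
  expect_equal(none$p_empirical, 1)
})

test_that("rank-sum p-values match enumeration, wilcox.test, and their
           normal approximation", {
  ## A = {1,2}, B = {3,4}: one-sided exact p = 1/6
  expect_equal(rank_sum_test(c(1, 2), c(3, 4),
                             alternative = "less")$p_value, 1 / 6)
  ## identical samples: p about 1
  same <- rank_sum_test(c(1, 2, 3), c(1, 2, 3))
  expect_gt(same$p_value, 0.9)
  ## exact agrees with wilcox.test on untied data
  withr::local_seed(8)
  a <- rnorm(7)
  b <- rnorm(6, 0.5)
  mine <- rank_sum_test(a, b)$p_value
  ref <- wilcox.test(a, b, exact = TRUE)$p.value
  expect_equal(mine, ref, tolerance = 1e-12)
  ## normal approximation within 10% of exact at n = 8 vs 8
  a8 <- rnorm(8)
  b8 <- rnorm(8, 1)
  ex <- rank_sum_test(a8, b8)$p_value
  ap <- rank_sum_test(a8, b8, exact_max = 0)$p_value
  expect_lt(abs(ap - ex) / ex, 0.1)
})

test_that("the rewiring z for shared annotations is positive and grows
           with the planted enrichment strength", {
  tr <- sim_truth(sim_params(seed = 19))
  net <- true_pairs(tr)
  zs <- vapply(c(0.1, 0.4, 0.8), function(enr) {
    maps <- sim_annotations(tr, co_complex_enrichment = enr)
    rewired_null(net, function(e)
      shared_annotation_fraction(e, maps$go),
      n_iter = 200, seed = 3)$z
  }, numeric(1))
  expect_true(all(diff(zs) > 0))
  expect_true(all(zs[2:3] > 0))
})

test_that("cell-envelope classification flags the envelope vocabulary", {
  ann <- tibble::tibble(
    protein = c("OmpX", "OmpX", "CytB", "NoAnn"),
    term = c("Integral component of membrane", "porin activity",
             "cytoplasm", "unknown"))
  cls <- classify_cell_envelope(ann)
  expect_true(cls$cell_envelope[cls$protein == "OmpX"])
  expect_false(cls$cell_envelope[cls$protein == "CytB"])
  expect_false(cls$cell_envelope[cls$protein == "NoAnn"])
  expect_equal(unname(attr(cls, "counts")["envelope"]), 1)
})
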