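test_that("gold-standard labelling follows the shared-complex rule", {
  g <- gold_standard(list(X = c("A", "B", "C"), Y = c("C", "D")))
  pairs <- tibble::tibble(protein_a = c("A", "A", "A", "C"),
                          protein_b = c("B", "D", "Z", "D"))
  lab <- build_gold_labels(g, pairs)
  expect_equal(lab$label, c("+", "-", NA, "+"))

  ## a single gold complex induces no negatives
  g1 <- gold_standard(list(X = c("A", "B", "C")))
  l1 <- build_gold_labels(g1, pairs)
  expect_false(any(l1$label %in% "-"))

  ## empty candidate list gives empty output
  expect_equal(nrow(build_gold_labels(g, pairs[0, ])), 0)
})

test_that("a perfectly separating feature ranks every positive above every
           negative with precision 1 down to the last positive", {
  n <- 24
  feats <- tibble::tibble(
    protein_a = sprintf("A%02d", 1:n), protein_b = sprintf("B%02d", 1:n),
    f1 = rep(c(1, 0), each = n / 2),
    label = rep(c("+", "-"), each = n / 2))
  sc <- score_pairs(feats, feature_cols = "f1", k_folds = 4, seed = 1)
  expect_true(min(sc$classifier_score[sc$label == "+"]) >
                max(sc$classifier_score[sc$label == "-"]))
  ca <- calibrate_interaction_scores(sc)
  expect_true(all(ca$curve$precision[seq_len(n / 2)] == 1))
})

test_that("naive Bayes posteriors match the Gaussian density-ratio oracle
           to 1e-9", {
  ## symmetric 1-D toy: query at the midpoint scores exactly 0.5
  X <- matrix(c(0.9, 1.1, -1.1, -0.9), ncol = 1)
  model <- coelute:::nb_train(X, c("+", "+", "-", "-"))
  expect_equal(coelute:::nb_posterior(model, matrix(0)), 0.5,
               tolerance = 1e-9)

  ## unequal class variances: hand-computed density ratio
  xp <- c(0, 0.4, 2.0)
  xn <- c(-1, -3)
  model2 <- coelute:::nb_train(matrix(c(xp, xn), ncol = 1),
                               c("+", "+", "+", "-", "-"))
  q <- c(-0.5, 0.3, 1.2)
  post <- coelute:::nb_posterior(model2, matrix(q, ncol = 1))
  oracle <- vapply(q, function(v) {
    lp <- dnorm(v, mean(xp), sd(xp)) * (3 / 5)
    ln <- dnorm(v, mean(xn), sd(xn)) * (2 / 5)
    lp / (lp + ln)
  }, numeric(1))
  expect_equal(post, oracle, tolerance = 1e-9)
})

test_that("posteriors agree with an independent naive Bayes
           implementation", {
  skip_if_not_installed("e1071")
  withr::local_seed(31)
  n <- 40
  X <- data.frame(f1 = c(rnorm(n, 1), rnorm(n, -1)),
                  f2 = c(rnorm(n, 0.5, 2), rnorm(n, 0, 0.5)))
  y <- rep(c("+", "-"), each = n)
  model <- coelute:::nb_train(as.matrix(X), y)
  mine <- coelute:::nb_posterior(model, as.matrix(X))
  ref <- e1071::naiveBayes(X, factor(y))
  theirs <- predict(ref, X, type = "raw", threshold = 0)[, "+"]
  expect_equal(mine, unname(theirs), tolerance = 1e-6)
})

test_that("missing feature values drop that feature's likelihood term", {
  X <- matrix(c(1, 1.2, 0.8, -1, -1.2, -0.8,
                5, 5.5, 4.5, -5, -4, -6), ncol = 2)
  y <- rep(c("+", "-"), each = 3)
  model <- coelute:::nb_train(X, y)
  with_na <- coelute:::nb_posterior(model, matrix(c(0.9, NA), ncol = 2))
  only_f1 <- coelute:::nb_posterior(
    coelute:::nb_train(X[, 1, drop = FALSE], y), matrix(0.9))
  expect_equal(with_na, only_f1, tolerance = 1e-12)
})

test_that("cross-validated scoring is deterministic and guards its fold
           requirement", {
  feats <- tibble::tibble(
    protein_a = sprintf("A%02d", 1:30), protein_b = sprintf("B%02d", 1:30),
    f1 = rnorm(30), label = c(rep(c("+", "-"), each = 10), rep(NA, 10)))
  s1 <- score_pairs(feats, feature_cols = "f1", k_folds = 5, seed = 9)
  s2 <- score_pairs(feats, feature_cols = "f1", k_folds = 5, seed = 9)
  expect_identical(s1, s2)
  expect_error(score_pairs(feats, feature_cols = "f1", k_folds = 11),
               "reduce k_folds")
})

test_that("interaction scores follow the cumulative TP/FP enumeration
           oracle", {
  sc <- tibble::tibble(
    protein_a = c("A", "B", "C"), protein_b = c("X", "Y", "Z"),
    classifier_score = c(0.9, 0.8, 0.7), label = c("+", "-", "+"))
  ca <- calibrate_interaction_scores(sc)
  expect_equal(ca$scores$interaction_score, c(1, 0.5, 2 / 3),
               tolerance = 1e-12)

  ## all-positive labels give interaction score 1 everywhere
  all_pos <- dplyr::mutate(sc, label = "+")
  expect_true(all(calibrate_interaction_scores(
    all_pos)$scores$interaction_score == 1))

  ## unlabelled pairs above the first labelled one inherit its precision
  sc2 <- tibble::tibble(
    protein_a = c("A", "B", "C"), protein_b = c("X", "Y", "Z"),
    classifier_score = c(0.95, 0.9, 0.8), label = c(NA, "+", "-"))
  ca2 <- calibrate_interaction_scores(sc2)
  expect_equal(ca2$scores$interaction_score, c(1, 1, 0.5))
  expect_equal(ca2$scores$precision_imputed, c(TRUE, FALSE, FALSE))
})

test_that("thresholding keeps the leading stretch above the target
           precision", {
  sc <- tibble::tibble(
    protein_a = c("A", "B", "C"), protein_b = c("X", "Y", "Z"),
    classifier_score = c(0.9, 0.8, 0.7), label = c("+", "-", "+"))
  ca <- calibrate_interaction_scores(sc)
  ## target 0.6: the second pair drops precision to 0.5, so only the top
  ## pair survives even though precision recovers to 2/3 afterwards
  top <- threshold_network(ca, target_precision = 0.6)
  expect_equal(nrow(top$edges), 1)
  expect_equal(top$edges$protein_a, "A")
  ## target 0: everything is returned
  all_net <- threshold_network(ca, target_precision = 0)
  expect_equal(nrow(all_net$edges), 3)
  ## unreachable target: empty network with a diagnostic, not an error
  expect_message(none <- threshold_network(ca, target_precision = 1.01),
                 "never attains")
  expect_equal(nrow(none$edges), 0)
})

test_that("with a fully labelled universe the truth-measured FDR matches
           1 - target precision", {
  ## generous labelled set: every protein in a known complex, so labels
  ## cover the entire candidate universe and precision is exact
  fdrs <- vapply(c(7, 8), function(s) {
    b <- sim_bundle(sim_params(complex_size_range = c(6, 6), seed = s),
                    known_fraction = 1)
    r <- run_chain(b, seed = s)
    truth_fdr(r$net, b$truth)
  }, numeric(1))
  expect_lt(max(abs(fdrs - 0.5)), 0.05)
})

test_that("predicted interactions have higher profile correlation than
           rejected candidate pairs", {
  b <- sim_bundle(sim_params(n_proteins = 80, n_complexes = 14, seed = 13))
  r <- run_chain(b, seed = 13)
  scores <- r$calib$scores
  in_net <- paste(scores$protein_a, scores$protein_b) %in%
    paste(r$net$edges$protein_a, r$net$edges$protein_b)
  r_pred <- mean(scores$pearson_r_rep1[in_net], na.rm = TRUE)
  r_rej <- mean(scores$pearson_r_rep1[!in_net], na.rm = TRUE)
  expect_gt(r_pred, r_rej)
})
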