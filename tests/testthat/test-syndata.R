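test_that("truth generation is deterministic and structurally valid", {
  p <- tiny_params()
  t1 <- sim_truth(p)
  t2 <- sim_truth(p)
  expect_identical(t1$complexes, t2$complexes)
  expect_identical(t1$assemblies, t2$assemblies)
  expect_identical(sim_profiles(t1), sim_profiles(t2))

  ## every protein is in a complex or monomeric
  covered <- union(unlist(t1$complexes), t1$monomers)
  expect_setequal(covered, sprintf("P%04d", 1:60))
  ## apexes on the fraction axis, widths positive
  expect_true(all(t1$assemblies$apex >= 1 &
                    t1$assemblies$apex <= p$n_fractions))
  expect_true(all(t1$assemblies$sigma > 0))
  ## true pair set is canonical and irreflexive
  tp <- true_pairs(t1)
  expect_true(all(tp$protein_a < tp$protein_b))
})

test_that("no complexes means all proteins monomeric with no true pairs", {
  tr <- sim_truth(sim_params(n_proteins = 20, n_complexes = 0, seed = 1))
  expect_length(tr$complexes, 0)
  expect_length(tr$monomers, 20)
  expect_equal(nrow(true_pairs(tr)), 0)
})

test_that("fixed-size complexes induce exactly n * choose(k, 2) true pairs", {
  tr <- sim_truth(sim_params(n_proteins = 100, n_complexes = 20,
                             complex_size_range = c(4, 4),
                             moonlight_rate = 0, seed = 3))
  ## enumeration oracle: count pairs complex by complex
  oracle <- sum(vapply(tr$complexes,
                       function(m) choose(length(m), 2), numeric(1)))
  expect_equal(oracle, 20 * choose(4, 2))
  expect_equal(nrow(true_pairs(tr)), 120)
})

test_that("an infeasible complex size draw is an explicit error", {
  expect_error(
    sim_truth(sim_params(n_proteins = 30, n_complexes = 10,
                         complex_size_range = c(5, 5),
                         monomer_fraction = 0.5, seed = 1)),
    "infeasible")
})

test_that("profile matrices have the configured fraction count and
           noiseless same-complex profiles correlate perfectly", {
  tr <- sim_truth(sim_params(n_proteins = 40, n_complexes = 8,
                             noise_sd = 0, missing_rate = 0,
                             detection_threshold = 0, apex_jitter = 0,
                             moonlight_rate = 0, seed = 2))
  profs <- sim_profiles(tr)
  expect_length(profs, 2)
  for (m in profs) {
    expect_equal(sum(startsWith(names(m), "fraction_")), 54)
  }
  feats <- compute_pair_features(profs[[1]])
  lab <- build_gold_labels(gold_standard(tr$complexes), feats)
  expect_true(all(abs(feats$pearson_r[lab$label %in% "+"] - 1) < 1e-12))
})

test_that("co-complex pairs correlate more than non-co-complex pairs under
           default noise", {
  ## Monte-Carlo oracle over the generator, > 1000 scored pairs
  tr <- sim_truth(sim_params(n_proteins = 80, n_complexes = 12, seed = 5))
  feats <- compute_pair_features(clean_profiles(sim_profiles(tr)[[1]]))
  lab <- build_gold_labels(gold_standard(tr$complexes), feats)
  expect_gt(nrow(feats), 1000)
  r_in <- mean(feats$pearson_r[lab$label %in% "+"], na.rm = TRUE)
  r_out <- mean(feats$pearson_r[is.na(lab$label) | lab$label == "-"],
                na.rm = TRUE)
  expect_gt(r_in, r_out)
})

test_that("larger assemblies elute earlier and more noise lowers
           co-complex correlation", {
  tr <- sim_truth(tiny_params())
  a <- tr$assemblies[order(tr$assemblies$mass), ]
  expect_true(all(diff(a$apex) <= 1e-12))

  mean_r <- function(noise, seed) {
    t2 <- sim_truth(sim_params(n_proteins = 50, n_complexes = 8,
                               noise_sd = noise, seed = seed))
    f <- compute_pair_features(clean_profiles(sim_profiles(t2)[[1]]))
    l <- build_gold_labels(gold_standard(t2$complexes), f)
    mean(f$pearson_r[l$label %in% "+"], na.rm = TRUE)
  }
  seeds <- 1:3
  r_by_noise <- vapply(c(0.1, 0.4, 0.8),
                       function(no) mean(vapply(seeds, mean_r,
                                                numeric(1), noise = no)),
                       numeric(1))
  expect_true(all(diff(r_by_noise) < 0))
})

test_that("co-expression generator hits its target correlations", {
  tr <- sim_truth(sim_params(n_proteins = 80, n_complexes = 15, seed = 6))
  ex <- sim_coexpression(tr, co_complex_r = 0.8, background_r = 0,
                         n_conditions = 200, coverage = 1)
  feats <- all_pairs(ex$protein) %>% coexpression_feature(ex)
  expect_false(any(feats$coexpression_imputed))
  lab <- build_gold_labels(gold_standard(tr$complexes), feats)
  r_in <- mean(feats$coexpression_r[lab$label %in% "+"])
  expect_lt(abs(r_in - 0.8), 0.05)

  ex0 <- sim_coexpression(tr, co_complex_r = 0, background_r = 0,
                          n_conditions = 200, coverage = 1)
  f0 <- coexpression_feature(all_pairs(ex0$protein), ex0)
  expect_lt(abs(mean(f0$coexpression_r)), 0.02)
})

test_that("phenotype generator gives ~50% positive correlations at zero
           signal and full-length condition vectors", {
  tr <- sim_truth(sim_params(n_proteins = 80, n_complexes = 15, seed = 7))
  ph <- sim_phenotypes(tr, co_complex_r = 0, n_conditions = 40,
                       coverage = 1)
  expect_equal(sum(startsWith(names(ph), "cond_")), 40)
  tp <- true_pairs(tr)
  frac <- phenotype_positive_fraction(tp, ph)
  expect_lt(abs(as.numeric(frac) - 0.5), 0.12)
})

test_that("annotation maps respect size bounds and carry no complex signal
           at zero enrichment", {
  tr <- sim_truth(sim_params(n_proteins = 100, n_complexes = 15, seed = 8))
  maps <- sim_annotations(tr, n_terms = 40, term_size_range = c(21, 50),
                          co_complex_enrichment = 0)
  sizes <- dplyr::count(maps$go, term)$n
  expect_true(all(sizes >= 21 & sizes <= 50))

  ## enumeration oracle over the emitted map: the shared-term rate of true
  ## pairs should match the all-pair background when terms ignore complexes
  tp <- true_pairs(tr)
  ap <- all_pairs(sprintf("P%04d", 1:100))
  f_true <- shared_annotation_fraction(tp, maps$go, min_count = -Inf,
                                       max_count = Inf)
  f_all <- shared_annotation_fraction(ap, maps$go, min_count = -Inf,
                                      max_count = Inf)
  expect_lt(abs(f_true - f_all), 0.1)
})

test_that("gold standard is a subset of the truth with consistent labels", {
  tr <- sim_truth(sim_params(n_proteins = 100, n_complexes = 20, seed = 9))
  g1 <- sim_gold_standard(tr, known_fraction = 1)
  expect_setequal(unique(g1$complex), names(tr$complexes))

  g5 <- sim_gold_standard(tr, known_fraction = 0.5)
  expect_length(unique(g5$complex), 10)

  ## every gold-induced "+" pair is a true co-complex pair
  lab <- build_gold_labels(g5, all_pairs(sprintf("P%04d", 1:100)))
  pos <- lab[lab$label %in% "+", c("protein_a", "protein_b")]
  tp <- true_pairs(tr)
  expect_equal(nrow(dplyr::anti_join(pos, tp,
                                     by = c("protein_a", "protein_b"))), 0)
})

test_that("external interactomes hit the requested recall and false count", {
  tr <- sim_truth(sim_params(n_proteins = 60, n_complexes = 10,
                             moonlight_rate = 0, seed = 10))
  tp <- true_pairs(tr)

  full <- sim_external_interactome(tr, true_edge_recall = 1,
                                   false_edge_count = 0)
  expect_equal(dplyr::arrange(full, protein_a, protein_b),
               dplyr::arrange(tp, protein_a, protein_b))

  none <- sim_external_interactome(tr, true_edge_recall = 0,
                                   false_edge_count = 30)
  expect_equal(network_overlap(none, tp), 0)

  half <- sim_external_interactome(tr, true_edge_recall = 0.5,
                                   false_edge_count = 0)
  expect_equal(nrow(half), round(0.5 * nrow(tp)))
  expect_equal(network_overlap(half, tp), nrow(half))
})

test_that("fixture bundles round-trip and regenerate byte-identically", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  params <- sim_params(n_proteins = 30, n_complexes = 5, seed = 77)
  bundle <- sim_bundle(params, annotations = list(term_size_range = c(5, 10),
                                                  n_terms = 10))
  manifest <- write_fixture_bundle(bundle, dir1)
  expect_true(file.exists(manifest))
  expect_equal(yaml::read_yaml(manifest)$seed, 77)

  back <- read_fixture_bundle(dir1)
  expect_equal(back$profiles[[1]], bundle$profiles[[1]],
               ignore_attr = TRUE)
  expect_equal(back$true_complexes, bundle$truth$complexes)

  ## regeneration from the manifest alone reproduces every file
  regenerate_bundle(manifest, dir2)
  for (f in list.files(dir1)) {
    expect_identical(readLines(file.path(dir2, f)),
                     readLines(file.path(dir1, f)),
                     label = paste("regenerated", f))
  }
})
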