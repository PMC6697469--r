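#' Default pipeline configuration
#'
#' One nested list holding every tunable of every stage. Unknown keys are
#' rejected, and the fully resolved configuration is written into the run
#' directory so a run is reproducible from its outputs alone. A single
#' global `seed` is expanded into independent per-stage streams.
#'
#' @param seed global seed.
#' @param label free-text run label.
#' @param ... overrides as nested lists, e.g.
#'   `simulate = list(n_proteins = 60)`, `predict = list(k_folds = 5)`.
#' @return object of class `pcp_config`.
#' @export
#' @examples
#' cfg <- pipeline_config(seed = 3, simulate = list(n_proteins = 60))
#' cfg$simulate$n_proteins
pipeline_config <- function(seed = 1L, label = "run", ...) {
  base <- list(
    seed = as.integer(seed),
    label = label,
    simulate = list(
      n_proteins = 150L, n_complexes = 25L, noise_sd = 0.35,
      missing_rate = 0.05, known_fraction = 0.6, moonlight_rate = 0.05,
      coexpression_r = 0.7, coexpression_background_r = 0.1,
      coexpression_coverage = 0.9, phenotype_r = 0.6,
      external_recall = 0.5, external_false_edges = 200L),
    cleaning = list(fill_scale = 0.01),
    peaks = list(max_components = 3L, min_height_frac = 0.1,
                 min_abs_height = 0.5),
    features = list(co_apex_window = 2),
    predict = list(k_folds = 10L, target_precision = 0.5),
    cluster = list(p = 50, dens = 0.001, inflation = 4, min_score = 0.5,
                   rescue_score = 0.75, use_grid = FALSE,
                   grid = list(p = c(0, 2, 50, 500, 5000),
                               dens = c(0.001, 0.1, 0.3),
                               inflation = c(2, 4, 10, 20),
                               min_score = c(0.5, 0.75))),
    validate = list(n_iter = 1000L, min_count = 20L, max_count = 1000L,
                    alpha = 0.05)
  )
  over <- list(...)
  merged <- merge_config(base, over, path = "config")
  structure(merged, class = "pcp_config")
}

merge_config <- function(base, over, path) {
  unknown <- setdiff(names(over), names(base))
  if (length(unknown)) {
    stop("unknown configuration key(s) under ", path, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (nm in names(over)) {
    if (is.list(base[[nm]]) && !is.null(names(base[[nm]])) &&
        is.list(over[[nm]]) && nm != "grid") {
      base[[nm]] <- merge_config(base[[nm]], over[[nm]],
                                 paste(path, nm, sep = "$"))
    } else {
      base[[nm]] <- over[[nm]]
    }
  }
  base
}

#' Read a resolved configuration back from a run directory
#' @param path a `config.yaml` written by [run_pipeline()].
#' @return a `pcp_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config,
          c(list(seed = raw$seed, label = raw$label),
            raw[setdiff(names(raw), c("seed", "label"))]))
}

#' Run the full co-fractionation analysis pipeline
#'
#' simulate -> clean -> fit peaks -> pairwise features -> gold labels ->
#' naive Bayes scoring -> precision calibration -> thresholded interactome
#' -> two-stage complex detection -> plausibility validation. Every
#' intermediate table is persisted as TSV in `outdir` together with the
#' resolved configuration, and the run report is recomputable from those
#' files via [pipeline_report()]. Fully deterministic given the
#' configuration seed.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (created).
#' @return object of class `pcp_run`: list with `report` (tibble of
#'   headline numbers), plus the in-memory stage objects (`truth`,
#'   `calibration`, `interactome`, `complexes`, `validation`).
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "pcp_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(...) message("[coelute] ", ...)

  cs <- config$simulate
  params <- sim_params(n_proteins = cs$n_proteins,
                       n_complexes = cs$n_complexes,
                       noise_sd = cs$noise_sd,
                       missing_rate = cs$missing_rate,
                       moonlight_rate = cs$moonlight_rate,
                       seed = config$seed)
  stage("simulate: ", cs$n_proteins, " proteins / ", cs$n_complexes,
        " complexes, seed ", config$seed)
  bundle <- sim_bundle(
    params, known_fraction = cs$known_fraction,
    coexpression = list(co_complex_r = cs$coexpression_r,
                        background_r = cs$coexpression_background_r,
                        coverage = cs$coexpression_coverage),
    phenotypes = list(co_complex_r = cs$phenotype_r),
    external = list(true_edge_recall = cs$external_recall,
                    false_edge_count = cs$external_false_edges))
  write_fixture_bundle(bundle, file.path(outdir, "input"))

  stage("clean + fit peaks on ", length(bundle$profiles), " replicate(s)")
  rules <- cleaning_rules(fill_scale = config$cleaning$fill_scale)
  cleaned <- lapply(bundle$profiles, clean_profiles, rules = rules)
  peaks <- lapply(cleaned, function(m)
    fit_peaks(m, max_components = config$peaks$max_components,
              min_height_frac = config$peaks$min_height_frac,
              min_abs_height = config$peaks$min_abs_height))

  stage("pairwise features")
  feats <- purrr::map2(cleaned, peaks, compute_pair_features,
                       co_apex_window = config$features$co_apex_window)
  features <- combine_replicate_features(feats) %>%
    coexpression_feature(bundle$coexpression)
  readr::write_tsv(features, file.path(outdir, "features.tsv"),
                   na = "", progress = FALSE)

  stage("label + score ", nrow(features), " candidate pairs")
  labelled <- build_gold_labels(bundle$gold, features)
  feature_cols <- setdiff(
    names(labelled)[vapply(labelled, is.numeric, logical(1))],
    "coexpression_imputed")
  scored <- score_pairs(labelled, feature_cols = feature_cols,
                        k_folds = config$predict$k_folds,
                        seed = config$seed)
  calib <- calibrate_interaction_scores(scored)
  readr::write_tsv(calib$scores, file.path(outdir, "scored_pairs.tsv"),
                   na = "", progress = FALSE)
  readr::write_tsv(calib$curve, file.path(outdir, "precision_curve.tsv"),
                   na = "", progress = FALSE)

  interactome <- threshold_network(calib, config$predict$target_precision)
  stage("interactome: ", interactome$summary$n_interactions,
        " interactions at target precision ",
        config$predict$target_precision)
  write_edge_list(interactome$edges, file.path(outdir, "network.tsv"))

  cc <- config$cluster
  if (isTRUE(cc$use_grid)) {
    stage("grid search over ", prod(lengths(cc$grid)), " parameter points")
    gs <- grid_search_params(interactome$edges, bundle$gold, grid = cc$grid,
                             rescue_score = cc$rescue_score)
    cparams <- gs$best_params
    readr::write_tsv(gs$table, file.path(outdir, "grid_search.tsv"),
                     progress = FALSE)
  } else {
    cparams <- clustering_params(p = cc$p, dens = cc$dens,
                                 inflation = cc$inflation,
                                 min_score = cc$min_score,
                                 rescue_score = cc$rescue_score)
  }
  cx <- two_stage_cluster(interactome$edges, cparams)
  stage("complexes: ", nrow(cx), " (median size ",
        if (nrow(cx)) median(cx$size) else NA, ")")
  write_complexes(cx, file.path(outdir, "complexes.tsv"))
  mmr_gold <- matching_ratio(cx, bundle$gold)$mmr

  stage("validation (", config$validate$n_iter, " null iterations)")
  cv <- config$validate
  vseed <- seed_streams(config$seed, c("go", "dom", "phe", "ovl"))
  val <- bind_rows(
    rewired_null(interactome, function(e)
      shared_annotation_fraction(e, bundle$annotations$go,
                                 cv$min_count, cv$max_count),
      n_iter = cv$n_iter, seed = vseed[["go"]], metric_name = "shared_go"),
    rewired_null(interactome, function(e)
      shared_annotation_fraction(e, bundle$annotations$domain,
                                 cv$min_count, cv$max_count),
      n_iter = cv$n_iter, seed = vseed[["dom"]],
      metric_name = "shared_domain"),
    rewired_null(interactome, function(e)
      phenotype_positive_fraction(e, bundle$phenotypes),
      n_iter = cv$n_iter, seed = vseed[["phe"]],
      metric_name = "phenotype_positive"),
    overlap_permutation_p(interactome, bundle$external[[1]],
                          n_iter = cv$n_iter, seed = vseed[["ovl"]])
  )
  hc <- high_confidence(interactome, bundle$external)
  enr <- complex_enrichment(cx, bundle$annotations$go, alpha = cv$alpha,
                            min_count = cv$min_count,
                            max_count = cv$max_count)
  ## clustered vs unclustered interaction scores
  inside <- purrr::map_dfr(cx$members, all_pairs) %>%
    distinct(.data$protein_a, .data$protein_b)
  edge_in <- semi_join(interactome$edges, inside,
                       by = c("protein_a", "protein_b"))
  edge_out <- anti_join(interactome$edges, inside,
                        by = c("protein_a", "protein_b"))
  score_cmp <- if (nrow(edge_in) && nrow(edge_out)) {
    rank_sum_test(edge_in$interaction_score, edge_out$interaction_score,
                  alternative = "greater")
  } else tibble(statistic = NA_real_, p_value = NA_real_, method = "n/a")
  readr::write_tsv(val, file.path(outdir, "validation.tsv"),
                   progress = FALSE)
  write_edge_list(hc, file.path(outdir, "high_confidence.tsv"))

  truth_edges <- true_pairs(bundle$truth)
  fdr_truth <- if (nrow(interactome$edges)) {
    1 - nrow(semi_join(interactome$edges, truth_edges,
                       by = c("protein_a", "protein_b"))) /
      nrow(interactome$edges)
  } else NA_real_

  report <- tibble(
    quantity = c("n_proteins", "n_candidate_pairs", "n_interactions",
                 "precision", "recall", "fdr_vs_truth", "n_complexes",
                 "median_complex_size", "mmr_vs_gold",
                 "n_clustered_pairs", "n_unclustered_pairs",
                 "mean_score_clustered", "mean_score_unclustered",
                 "rank_sum_p", "n_high_confidence", "n_enriched_complexes",
                 "z_shared_go", "z_shared_domain", "z_phenotype",
                 "overlap_external_1", "overlap_p"),
    value = c(cs$n_proteins, nrow(features),
              interactome$summary$n_interactions,
              interactome$summary$precision, interactome$summary$recall,
              fdr_truth, nrow(cx),
              if (nrow(cx)) median(cx$size) else NA_real_, mmr_gold,
              nrow(edge_in), nrow(edge_out),
              mean(edge_in$interaction_score),
              mean(edge_out$interaction_score),
              score_cmp$p_value, nrow(hc), enr$n_enriched,
              val$z[val$metric == "shared_go"],
              val$z[val$metric == "shared_domain"],
              val$z[val$metric == "phenotype_positive"],
              val$observed[val$metric == "overlap"],
              val$p_empirical[val$metric == "overlap"]))
  readr::write_tsv(report, file.path(outdir, "report.tsv"), progress = FALSE)
  yaml::write_yaml(unclass(config), file.path(outdir, "config.yaml"),
                   precision = 17)

  structure(list(report = report, truth = bundle$truth,
                 calibration = calib, interactome = interactome,
                 complexes = cx, validation = val,
                 high_confidence = hc, enrichment = enr,
                 config = config, outdir = outdir),
            class = "pcp_run")
}

#' @export
print.pcp_run <- function(x, ...) {
  cat("<pcp_run> '", x$config$label, "' in ", x$outdir, "\n", sep = "")
  print(x$report, n = Inf)
  invisible(x)
}

write_complexes <- function(cx, path) {
  readr::write_tsv(
    tibble(complex = cx$complex, provenance = cx$provenance,
           members = vapply(cx$members, paste, character(1),
                            collapse = ";")),
    path, progress = FALSE)
  invisible(path)
}

#' Read a complexes TSV back as a `pcp_complexes` tibble
#' @param path file written by a pipeline run.
#' @return `pcp_complexes` tibble.
#' @export
read_complexes <- function(path) {
  raw <- readr::read_tsv(path, col_types = "ccc", progress = FALSE)
  out <- tibble(complex = raw$complex, provenance = raw$provenance,
                members = strsplit(raw$members, ";", fixed = TRUE))
  out$size <- lengths(out$members)
  out <- out[, c("complex", "provenance", "size", "members")]
  structure(out, class = c("pcp_complexes", class(out)))
}

#' Regenerate the run report from a run directory's persisted files
#'
#' Recomputes every headline number from the stage outputs on disk, without
#' re-running any stage — proving the persisted tables are sufficient to
#' audit the run. A missing stage file is a clear error naming it.
#'
#' @param outdir directory written by [run_pipeline()].
#' @return tibble like the `report` element of [run_pipeline()].
#' @export
pipeline_report <- function(outdir) {
  need <- function(f) {
    path <- file.path(outdir, f)
    if (!file.exists(path)) {
      stop("missing stage output: ", path, call. = FALSE)
    }
    path
  }
  config <- read_pipeline_config(need("config.yaml"))
  features <- readr::read_tsv(need("features.tsv"),
                              col_types = readr::cols(), progress = FALSE)
  scores <- readr::read_tsv(need("scored_pairs.tsv"),
                            col_types = readr::cols(), progress = FALSE)
  network <- read_edge_list(need("network.tsv"))
  cx <- read_complexes(need("complexes.tsv"))
  val <- readr::read_tsv(need("validation.tsv"),
                         col_types = readr::cols(), progress = FALSE)
  hc <- read_edge_list(need("high_confidence.tsv"))
  stored <- readr::read_tsv(need("report.tsv"),
                            col_types = readr::cols(), progress = FALSE)
  truth_cx <- read_complex_list(need(file.path("input",
                                               "true_complexes.tsv")))
  gold_cx <- read_complex_list(need(file.path("input",
                                              "gold_complexes.tsv")))
  ann_go <- read_annotation_map(need(file.path("input",
                                               "annotations_go.tsv")))

  truth_edges <- purrr::map_dfr(truth_cx, all_pairs) %>%
    distinct(.data$protein_a, .data$protein_b)
  net_lab <- network$label[!is.na(network$label)]
  total_pos <- sum(scores$label == "+", na.rm = TRUE)
  inside <- purrr::map_dfr(cx$members, all_pairs) %>%
    distinct(.data$protein_a, .data$protein_b)
  edge_in <- semi_join(network, inside, by = c("protein_a", "protein_b"))
  edge_out <- anti_join(network, inside, by = c("protein_a", "protein_b"))
  score_cmp <- if (nrow(edge_in) && nrow(edge_out)) {
    rank_sum_test(edge_in$interaction_score, edge_out$interaction_score,
                  alternative = "greater")
  } else tibble(p_value = NA_real_)
  enr <- complex_enrichment(cx, ann_go, alpha = config$validate$alpha,
                            min_count = config$validate$min_count,
                            max_count = config$validate$max_count)
  precision <- sum(net_lab == "+") / max(1, sum(net_lab != ""))
  tibble(
    quantity = stored$quantity,
    value = c(
      config$simulate$n_proteins, nrow(features), nrow(network),
      precision,
      sum(net_lab == "+") / max(1, total_pos),
      1 - nrow(semi_join(network, truth_edges,
                         by = c("protein_a", "protein_b"))) /
        max(1, nrow(network)),
      nrow(cx), median(cx$size),
      matching_ratio(cx, gold_standard(gold_cx))$mmr,
      nrow(edge_in), nrow(edge_out),
      mean(edge_in$interaction_score), mean(edge_out$interaction_score),
      score_cmp$p_value, nrow(hc), enr$n_enriched,
      val$z[val$metric == "shared_go"],
      val$z[val$metric == "shared_domain"],
      val$z[val$metric == "phenotype_positive"],
      val$observed[val$metric == "overlap"],
      val$p_empirical[val$metric == "overlap"]))
}
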