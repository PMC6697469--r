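#' Label candidate pairs from a gold standard
#'
#' A pair is labelled `"+"` (interacting) when both members share at least
#' one gold complex, `"-"` (non-interacting) when both members appear
#' somewhere in the gold standard but never in the same complex, and `NA`
#' (unlabelled) otherwise. The three labels are mutually exclusive by
#' construction.
#'
#' @param gold a `pcp_gold` tibble (`complex`, `protein`), e.g. from
#'   [sim_gold_standard()] or [gold_standard()].
#' @param pairs tibble of candidate pairs (`protein_a`, `protein_b`).
#' @return `pairs` plus a `label` column (`"+"`, `"-"`, or `NA`).
#' @export
#' @examples
#' g <- gold_standard(list(X = c("A", "B", "C"), Y = c("C", "D")))
#' p <- tibble::tibble(protein_a = c("A", "A"), protein_b = c("B", "D"))
#' build_gold_labels(g, p)$label  # "+" then "-"
build_gold_labels <- function(gold, pairs) {
  stopifnot(nrow(gold) > 0)
  if (!nrow(pairs)) return(mutate(pairs, label = character()))
  gold_pairs <- purrr::map_dfr(gold_complex_list(gold), all_pairs) %>%
    distinct(.data$protein_a, .data$protein_b)
  pos <- pair_key(pairs$protein_a, pairs$protein_b) %in%
    pair_key(gold_pairs$protein_a, gold_pairs$protein_b)
  in_gold <- pairs$protein_a %in% gold$protein &
    pairs$protein_b %in% gold$protein
  mutate(pairs, label = dplyr::case_when(
    pos ~ "+",
    in_gold ~ "-",
    TRUE ~ NA_character_))
}

## ---- Gaussian naive Bayes (internal) --------------------------------------
## class-conditional univariate Gaussians; missing feature values are
## handled by dropping that feature's likelihood term for that observation.

nb_train <- function(X, y, var_floor = 1e-9) {
  ## radix sort: class order must not depend on the session locale
  classes <- sort(unique(y), method = "radix")
  stats_by_class <- lapply(classes, function(cl) {
    Xc <- X[y == cl, , drop = FALSE]
    mu <- apply(Xc, 2, function(v) mean(v, na.rm = TRUE))
    vr <- apply(Xc, 2, function(v) {
      v <- v[!is.na(v)]
      if (length(v) < 2) return(NA_real_)
      stats::var(v)
    })
    list(mu = mu, var = pmax(vr, var_floor))
  })
  names(stats_by_class) <- classes
  prior <- table(y)[classes] / length(y)
  structure(list(classes = classes, stats = stats_by_class,
                 prior = as.numeric(prior)), class = "nb_model")
}

## posterior P(class = "+") for each row of X
nb_posterior <- function(model, X) {
  loglik <- vapply(seq_along(model$classes), function(ci) {
    st <- model$stats[[ci]]
    ll <- rep(log(model$prior[ci]), nrow(X))
    for (j in seq_len(ncol(X))) {
      x <- X[, j]
      ok <- !is.na(x) & !is.na(st$mu[j]) & !is.na(st$var[j])
      ll[ok] <- ll[ok] + dnorm(x[ok], st$mu[j], sqrt(st$var[j]), log = TRUE)
    }
    ll
  }, numeric(nrow(X)))
  if (nrow(X) == 1) loglik <- matrix(loglik, nrow = 1)
  mx <- apply(loglik, 1, max)
  post <- exp(loglik - mx)
  post <- post / rowSums(post)
  post[, match("+", model$classes)]
}

#' Score candidate pairs with a cross-validated naive Bayes classifier
#'
#' Labelled pairs are split into `k_folds` stratified folds; each labelled
#' pair's score is the posterior probability of "interacting" from the model
#' trained without its fold, so no labelled pair is scored by a model that
#' saw it. Unlabelled pairs are scored by the average posterior across the
#' `k` fold models. The class-conditional model is a univariate Gaussian per
#' feature; a missing feature value simply omits that feature's likelihood
#' term. Class priors come from label frequencies.
#'
#' @param features tibble with `protein_a`, `protein_b`, a `label` column
#'   from [build_gold_labels()], and numeric feature columns.
#' @param feature_cols character vector of feature column names; defaults to
#'   every numeric column except identifiers.
#' @param k_folds number of cross-validation folds (default 10).
#' @param seed seed for the fold assignment.
#' @return `features` plus `classifier_score` in `[0, 1]`.
#' @export
score_pairs <- function(features, feature_cols = NULL, k_folds = 10,
                        seed = 1L) {
  stopifnot("label" %in% names(features))
  if (is.null(feature_cols)) {
    feature_cols <- names(features)[vapply(features, is.numeric, logical(1))]
    feature_cols <- setdiff(feature_cols, c("classifier_score",
                                            "interaction_score"))
  }
  X <- as.matrix(features[feature_cols])
  y <- features$label
  lab_idx <- which(!is.na(y))
  classes <- sort(unique(y[lab_idx]), method = "radix")
  counts <- vapply(classes, function(cl) sum(y[lab_idx] == cl), integer(1))
  if (length(counts) < 2 || any(counts < k_folds)) {
    stop("each class needs at least k_folds = ", k_folds,
         " labelled pairs (have ",
         paste(names(counts), counts, sep = "=", collapse = ", "),
         "); reduce k_folds", call. = FALSE)
  }
  folds <- integer(length(y))
  with_rng(seed, {
    for (cl in classes) {
      idx <- lab_idx[y[lab_idx] == cl]
      folds[idx] <- sample(rep_len(seq_len(k_folds), length(idx)))
    }
  })
  score <- rep(NA_real_, length(y))
  unl <- which(is.na(y))
  unl_acc <- matrix(0, length(unl), k_folds)
  for (f in seq_len(k_folds)) {
    train <- lab_idx[folds[lab_idx] != f]
    model <- nb_train(X[train, , drop = FALSE], y[train])
    held <- lab_idx[folds[lab_idx] == f]
    if (length(held)) {
      score[held] <- nb_posterior(model, X[held, , drop = FALSE])
    }
    if (length(unl)) {
      unl_acc[, f] <- nb_posterior(model, X[unl, , drop = FALSE])
    }
  }
  if (length(unl)) score[unl] <- rowMeans(unl_acc)
  mutate(features, classifier_score = score)
}

#' Calibrate classifier scores to precision-based interaction scores
#'
#' Pairs are ranked by descending classifier score (ties broken
#' lexicographically by pair id). Walking down the ranking, each pair's
#' interaction score is the precision TP / (TP + FP) among the labelled
#' pairs at or above its position; unlabelled pairs inherit the precision at
#' their position. Positions above the first labelled pair, where precision
#' is undefined, take the first defined value below them and are flagged.
#' 1 - interaction score is the estimated false discovery rate of the list
#' down to that pair.
#'
#' @param scored tibble from [score_pairs()] (needs `classifier_score` and
#'   `label`).
#' @return object of class `pcp_calibration`: list with `scores` (the input
#'   plus `interaction_score` and `precision_imputed`, in rank order) and
#'   `curve` (a precision-recall curve tibble: `rank`, `threshold`, `tp`,
#'   `fp`, `precision`, `recall`).
#' @export
calibrate_interaction_scores <- function(scored) {
  stopifnot(all(c("classifier_score", "label") %in% names(scored)))
  sc <- arrange(scored, desc(.data$classifier_score), .data$protein_a,
                .data$protein_b)
  tp <- cumsum(!is.na(sc$label) & sc$label == "+")
  fp <- cumsum(!is.na(sc$label) & sc$label == "-")
  denom <- tp + fp
  if (max(denom) == 0) {
    stop("no labelled pairs: interaction scores are undefined",
         call. = FALSE)
  }
  precision <- ifelse(denom > 0, tp / denom, NA_real_)
  imputed <- is.na(precision)
  if (any(imputed)) {
    first_def <- which(!imputed)[1]
    precision[seq_len(first_def - 1)] <- precision[first_def]
  }
  total_pos <- max(tp)
  curve <- tibble(rank = seq_len(nrow(sc)),
                  threshold = sc$classifier_score,
                  tp = tp, fp = fp, precision = precision,
                  recall = if (total_pos > 0) tp / total_pos else NA_real_)
  scores <- mutate(sc, interaction_score = precision,
                   precision_imputed = imputed)
  structure(list(scores = scores, curve = curve), class = "pcp_calibration")
}

#' @export
print.pcp_calibration <- function(x, ...) {
  cat("<pcp_calibration> ", nrow(x$scores), " scored pairs (",
      sum(x$scores$label == "+", na.rm = TRUE), " '+', ",
      sum(x$scores$label == "-", na.rm = TRUE), " '-'); list precision ",
      round(min(x$curve$precision[nrow(x$curve)]), 3), "\n", sep = "")
  invisible(x)
}

#' Threshold the calibrated ranking into an interactome
#'
#' Walks down the ranking and keeps the leading stretch over which the
#' cumulative precision stays at or above `target_precision`: the network
#' is the prefix ending just before the precision first drops below the
#' target. If the curve is below the target from the start, the network is
#' empty and a diagnostic is attached rather than an error thrown.
#'
#' @param calibration a [calibrate_interaction_scores()] result.
#' @param target_precision minimum interaction score retained (default 0.50,
#'   i.e. a 50 percent FDR list).
#' @return object of class `pcp_interactome`: list with `edges` (tibble
#'   `protein_a`, `protein_b`, `classifier_score`, `interaction_score`,
#'   `label`) and `summary` (tibble: `n_interactions`, `precision`,
#'   `recall`, `fdr`, `target_precision`). `recall` is computed over gold
#'   "+" pairs present among the candidates.
#' @export
threshold_network <- function(calibration, target_precision = 0.5) {
  stopifnot(inherits(calibration, "pcp_calibration"))
  sc <- calibration$scores
  below <- which(sc$interaction_score < target_precision)
  cut <- if (length(below)) below[1] - 1 else nrow(sc)
  edges <- sc[seq_len(cut), c("protein_a", "protein_b", "classifier_score",
                              "interaction_score", "label")]
  lab_in <- edges$label[!is.na(edges$label)]
  tp_in <- sum(lab_in == "+")
  fp_in <- sum(lab_in == "-")
  total_pos <- sum(sc$label == "+", na.rm = TRUE)
  precision <- if (tp_in + fp_in > 0) tp_in / (tp_in + fp_in) else NA_real_
  out <- list(
    edges = as_tibble(edges),
    summary = tibble(
      n_interactions = nrow(edges),
      precision = precision,
      recall = if (total_pos > 0) tp_in / total_pos else NA_real_,
      fdr = 1 - precision,
      target_precision = target_precision)
  )
  if (!nrow(edges)) {
    out$diagnostic <- paste0("precision curve never attains target ",
                             target_precision, "; empty network")
    message(out$diagnostic)
  }
  structure(out, class = "pcp_interactome")
}

#' @export
print.pcp_interactome <- function(x, ...) {
  s <- x$summary
  cat("<pcp_interactome> ", s$n_interactions, " interactions at target ",
      s$target_precision, " (precision ", round(s$precision, 3),
      ", recall ", round(s$recall, 3), ")\n", sep = "")
  invisible(x)
}
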