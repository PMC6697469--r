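#' Cleaning rules for co-fractionation profiles
#'
#' @param remove_spikes drop isolated single-point spikes (an observed value
#'   flanked by missing values on both sides; edge fractions are never
#'   spikes).
#' @param impute_interior impute a single interior missing value as the mean
#'   of its two observed neighbours.
#' @param fill_missing replace any remaining missing value with near-zero
#'   noise so that distances are defined on previously gappy profiles.
#' @param fill_scale the near-zero fill is drawn uniformly from
#'   `[0, fill_scale * max(matrix)]`.
#' @param seed fixed seed for the near-zero fill, making cleaning
#'   deterministic and idempotent.
#' @return a `cleaning_rules` list.
#' @export
cleaning_rules <- function(remove_spikes = TRUE, impute_interior = TRUE,
                           fill_missing = TRUE, fill_scale = 0.01,
                           seed = 42L) {
  structure(list(remove_spikes = remove_spikes,
                 impute_interior = impute_interior,
                 fill_missing = fill_missing,
                 fill_scale = fill_scale, seed = as.integer(seed)),
            class = "cleaning_rules")
}

profile_matrix_values <- function(profiles) {
  stopifnot(is.data.frame(profiles), "protein" %in% names(profiles))
  m <- as.matrix(profiles[setdiff(names(profiles), "protein")])
  rownames(m) <- profiles$protein
  storage.mode(m) <- "double"
  m
}

values_to_profiles <- function(m, template) {
  out <- dplyr::bind_cols(tibble(protein = rownames(m)),
                          as_tibble(m, .name_repair = "minimal"))
  attr(out, "replicate") <- attr(template, "replicate")
  out
}

#' Clean a profile matrix
#'
#' Applies, in order: (i) spike removal — an observed value whose two
#' immediate neighbours are both missing is set to missing (interior
#' fractions only); (ii) single-gap imputation — an interior missing value
#' with observed values on both sides becomes the mean of those neighbours;
#' (iii) near-zero fill — all remaining missing values are replaced by small
#' positive noise drawn with the rules' fixed seed. The output has no
#' missing values; the input is not modified. Cleaning an already clean
#' matrix is a no-op.
#'
#' @param profiles tibble `protein` + fraction columns.
#' @param rules a [cleaning_rules()] object.
#' @return cleaned tibble of the same shape.
#' @export
#' @examples
#' m <- tibble::tibble(protein = "P1", fraction_1 = 2, fraction_2 = NA,
#'                     fraction_3 = 4)
#' clean_profiles(m)$fraction_2  # 3, the neighbour mean
clean_profiles <- function(profiles, rules = cleaning_rules()) {
  m <- profile_matrix_values(profiles)
  nf <- ncol(m)
  if (rules$remove_spikes && nf >= 3) {
    obs <- !is.na(m)
    interior <- 2:(nf - 1)
    spike <- obs
    spike[] <- FALSE
    spike[, interior] <- obs[, interior] &
      !obs[, interior - 1, drop = FALSE] & !obs[, interior + 1, drop = FALSE]
    m[spike] <- NA_real_
  }
  if (rules$impute_interior && nf >= 3) {
    obs <- !is.na(m)
    interior <- 2:(nf - 1)
    gap <- !obs[, interior, drop = FALSE] &
      obs[, interior - 1, drop = FALSE] & obs[, interior + 1, drop = FALSE]
    idx <- which(gap, arr.ind = TRUE)
    if (nrow(idx)) {
      cols <- interior[idx[, 2]]
      m[cbind(idx[, 1], cols)] <-
        (m[cbind(idx[, 1], cols - 1)] + m[cbind(idx[, 1], cols + 1)]) / 2
    }
  }
  if (rules$fill_missing) {
    miss <- is.na(m)
    if (any(miss)) {
      top <- if (all(miss)) 1 else max(m, na.rm = TRUE)
      if (!is.finite(top) || top <= 0) top <- 1
      fill <- with_rng(rules$seed,
                               runif(sum(miss), 0, rules$fill_scale * top))
      m[miss] <- fill
    }
  }
  values_to_profiles(m, profiles)
}

## sum of k Gaussians evaluated at x; par = (A1..Ak, mu1..muk, s1..sk)
gauss_mix <- function(par, x) {
  k <- length(par) / 3
  A <- par[seq_len(k)]
  mu <- par[k + seq_len(k)]
  s <- par[2 * k + seq_len(k)]
  rowSums(vapply(seq_len(k),
                 function(i) A[i] * exp(-(x - mu[i])^2 / (2 * s[i]^2)),
                 numeric(length(x))))
}

fit_gauss_mix <- function(y, k) {
  x <- seq_along(y)
  n <- length(y)
  ## start centres at the k highest local maxima (padded by quantiles)
  d <- diff(y)
  locmax <- which(c(FALSE, d[-length(d)] > 0 & d[-1] <= 0, FALSE))
  if (y[1] > y[2]) locmax <- c(1L, locmax)
  if (y[n] > y[n - 1]) locmax <- c(locmax, n)
  locmax <- locmax[order(y[locmax], decreasing = TRUE)]
  centres <- head(locmax, k)
  if (length(centres) < k) {
    centres <- c(centres,
                 round(quantile(x, seq(0.2, 0.8,
                                       length.out = k - length(centres)))))
  }
  par0 <- c(pmax(y[centres], 1e-3), as.numeric(centres), rep(2, k))
  lower <- c(rep(0, k), rep(0.5, k), rep(0.4, k))
  upper <- c(rep(2 * max(y), k), rep(n + 0.5, k), rep(n, k))
  fit <- try(minpack.lm::nls.lm(
    par = par0, lower = lower, upper = upper,
    fn = function(p) y - gauss_mix(p, x),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error")) return(NULL)
  rss <- sum(fit$fvec^2)
  list(par = fit$par, rss = rss,
       bic = n * log(max(rss, 1e-12) / n) + 3 * k * log(n))
}

#' Fit Gaussian elution peaks to cleaned profiles
#'
#' Per protein, fits mixtures of 1 to `max_components` Gaussians by
#' nonlinear least squares and selects the component count by BIC.
#' Components below `min_height_frac` of the profile maximum (or below an
#' absolute floor) are discarded; proteins where no fit converges, or whose
#' profile never rises above the floor, get an empty peak list — never an
#' exception.
#'
#' @param profiles cleaned tibble `protein` + fraction columns.
#' @param max_components maximum number of Gaussian components per protein.
#' @param min_height_frac minimum component height, as a fraction of the
#'   protein's profile maximum.
#' @param min_abs_height absolute minimum profile maximum for a protein to
#'   be fit at all.
#' @return tibble `protein`, `component`, `mu`, `sigma`, `height`, `rss`,
#'   class `pcp_peaks`; components are sorted by `mu` within protein.
#'   Proteins with no surviving component are absent.
#' @export
fit_peaks <- function(profiles, max_components = 3, min_height_frac = 0.1,
                      min_abs_height = 0.5) {
  m <- profile_matrix_values(profiles)
  res <- purrr::map_dfr(rownames(m), function(pr) {
    y <- m[pr, ]
    if (!any(is.finite(y)) || max(y, na.rm = TRUE) < min_abs_height) {
      return(tibble())
    }
    y[!is.finite(y)] <- 0
    best <- NULL
    for (k in seq_len(max_components)) {
      f <- fit_gauss_mix(y, k)
      if (!is.null(f) && (is.null(best) || f$bic < best$bic)) {
        best <- f
        best$k <- k
      }
    }
    if (is.null(best)) return(tibble())
    k <- best$k
    A <- best$par[seq_len(k)]
    mu <- pmin(pmax(best$par[k + seq_len(k)], 1), ncol(m))
    s <- best$par[2 * k + seq_len(k)]
    keep <- A >= max(min_height_frac * max(y), min_abs_height * 0.5)
    if (!any(keep)) return(tibble())
    tibble(protein = pr, mu = mu[keep], sigma = s[keep], height = A[keep],
           rss = best$rss) %>%
      arrange(.data$mu) %>%
      mutate(component = row_number(), .after = "protein")
  })
  if (!nrow(res)) {
    res <- tibble(protein = character(), component = integer(),
                  mu = double(), sigma = double(), height = double(),
                  rss = double())
  }
  structure(res, class = c("pcp_peaks", class(res)))
}

#' Pairwise similarity features from one replicate
#'
#' For every unordered pair of proteins present in the matrix: Pearson
#' correlation and Euclidean distance over the fraction axis (profiles
#' max-normalised per protein first, unless `normalize = FALSE`), and a
#' binary co-apex flag — 1 when some pair of fitted peak centres differ by
#' at most `co_apex_window` fractions, `NA` when either protein has no
#' fitted peak.
#'
#' @param profiles cleaned tibble `protein` + fraction columns.
#' @param peaks a [fit_peaks()] result for the same matrix (optional; when
#'   omitted the co-apex feature is `NA`).
#' @param co_apex_window maximum apex separation (fractions) still counted
#'   as co-eluting.
#' @param normalize divide each profile by its maximum before computing
#'   distance (Pearson correlation is scale-invariant either way).
#' @return tibble `protein_a`, `protein_b`, `replicate`, `pearson_r`,
#'   `euclidean_dist`, `co_apex`.
#' @export
compute_pair_features <- function(profiles, peaks = NULL, co_apex_window = 2,
                                  normalize = TRUE) {
  m <- profile_matrix_values(profiles)
  if (normalize) {
    mx <- apply(m, 1, max)
    mx[mx <= 0] <- 1
    m <- m / mx
  }
  prots <- rownames(m)
  pairs <- all_pairs(prots)
  if (!nrow(pairs)) {
    return(tibble(protein_a = character(), protein_b = character(),
                  replicate = character(), pearson_r = double(),
                  euclidean_dist = double(), co_apex = double()))
  }
  R <- suppressWarnings(cor(t(m)))
  D <- as.matrix(dist(m))
  ia <- match(pairs$protein_a, prots)
  ib <- match(pairs$protein_b, prots)
  co_apex <- rep(NA_real_, nrow(pairs))
  if (!is.null(peaks) && nrow(peaks)) {
    mus <- split(peaks$mu, peaks$protein)
    ma <- mus[pairs$protein_a]
    mb <- mus[pairs$protein_b]
    co_apex <- unname(purrr::map2_dbl(ma, mb, function(u, v) {
      if (is.null(u) || is.null(v)) return(NA_real_)
      as.numeric(min(abs(outer(u, v, "-"))) <= co_apex_window)
    }))
  }
  tibble(protein_a = pairs$protein_a, protein_b = pairs$protein_b,
         replicate = attr(profiles, "replicate") %||% "rep1",
         pearson_r = R[cbind(ia, ib)],
         euclidean_dist = D[cbind(ia, ib)],
         co_apex = co_apex)
}

#' Combine per-replicate features into one record per pair
#'
#' The candidate-pair universe is every pair co-quantified in at least one
#' replicate; a pair missing from a replicate gets `NA` for that
#' replicate's features (the classifier later drops missing feature terms).
#'
#' @param feature_list list of [compute_pair_features()] tibbles.
#' @return wide tibble `protein_a`, `protein_b`,
#'   `<feature>_<replicate>` columns.
#' @export
combine_replicate_features <- function(feature_list) {
  long <- bind_rows(feature_list)
  tidyr::pivot_wider(long,
                     id_cols = c("protein_a", "protein_b"),
                     names_from = "replicate",
                     values_from = c("pearson_r", "euclidean_dist",
                                     "co_apex")) %>%
    arrange(.data$protein_a, .data$protein_b)
}

#' Co-expression feature with mean imputation
#'
#' Pairs covered by the expression matrix get the Pearson correlation of
#' their condition vectors; uncovered pairs are imputed as the mean of all
#' computed correlations and flagged. An empty expression matrix yields 0
#' for every pair, flagged imputed, with a warning.
#'
#' @param pairs tibble with `protein_a`, `protein_b`.
#' @param expression tibble `protein` + condition columns, possibly covering
#'   only a subset of proteins.
#' @return `pairs` plus `coexpression_r` and `coexpression_imputed`.
#' @export
coexpression_feature <- function(pairs, expression) {
  stopifnot(all(c("protein_a", "protein_b") %in% names(pairs)))
  if (is.null(expression) || nrow(expression) == 0) {
    warning("empty expression matrix: all co-expression values imputed as 0",
            call. = FALSE)
    return(mutate(pairs, coexpression_r = 0, coexpression_imputed = TRUE))
  }
  em <- profile_matrix_values(expression)
  ia <- match(pairs$protein_a, rownames(em))
  ib <- match(pairs$protein_b, rownames(em))
  covered <- !is.na(ia) & !is.na(ib)
  r <- rep(NA_real_, nrow(pairs))
  if (any(covered)) {
    cm <- suppressWarnings(cor(t(em)))
    r[covered] <- cm[cbind(ia[covered], ib[covered])]
  }
  fallback <- if (any(!is.na(r))) mean(r, na.rm = TRUE) else 0
  if (all(is.na(r))) {
    warning("no pair covered by the expression matrix: imputing 0",
            call. = FALSE)
  }
  imputed <- is.na(r)
  r[imputed] <- fallback
  mutate(pairs, coexpression_r = r, coexpression_imputed = imputed)
}
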