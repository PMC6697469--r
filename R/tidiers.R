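#' Broom-style tidiers for coelute result objects
#'
#' `tidy()` returns the per-observation table of a result (ranked scored
#' pairs, matched complex pairs, per-test enrichment rows); `glance()`
#' returns a one-row summary.
#'
#' @param x a coelute result object.
#' @param ... unused.
#' @name coelute-tidiers
NULL

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @rdname coelute-tidiers
#' @export
tidy.pcp_calibration <- function(x, ...) x$scores

#' @rdname coelute-tidiers
#' @export
glance.pcp_calibration <- function(x, ...) {
  last <- x$curve[nrow(x$curve), ]
  tibble(n_pairs = nrow(x$scores),
         n_labelled_pos = sum(x$scores$label == "+", na.rm = TRUE),
         n_labelled_neg = sum(x$scores$label == "-", na.rm = TRUE),
         list_precision = last$precision, list_recall = last$recall)
}

#' @rdname coelute-tidiers
#' @export
tidy.pcp_interactome <- function(x, ...) x$edges

#' @rdname coelute-tidiers
#' @export
glance.pcp_interactome <- function(x, ...) x$summary

#' @rdname coelute-tidiers
#' @export
tidy.pcp_complexes <- function(x, ...) {
  tidyr::unnest(
    tibble(complex = x$complex, provenance = x$provenance,
           protein = x$members),
    "protein")
}

#' @rdname coelute-tidiers
#' @export
glance.pcp_complexes <- function(x, ...) {
  tibble(n_complexes = nrow(x),
         median_size = if (nrow(x)) median(x$size) else NA_real_,
         n_rescue = sum(x$provenance == "rescue"),
         n_proteins = length(unique(unlist(x$members))))
}

#' @rdname coelute-tidiers
#' @export
tidy.pcp_match <- function(x, ...) x$matches

#' @rdname coelute-tidiers
#' @export
glance.pcp_match <- function(x, ...) {
  tibble(mmr = x$mmr, n_matched = nrow(x$matches),
         n_predicted = nrow(x$omega), n_reference = ncol(x$omega))
}

#' @rdname coelute-tidiers
#' @export
tidy.pcp_validation <- function(x, ...) {
  tibble(null_value = attr(x, "null_values"))
}

#' @rdname coelute-tidiers
#' @export
glance.pcp_validation <- function(x, ...) as_tibble(as.data.frame(x))
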