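fraction_cols <- function(n) sprintf("fraction_%d", seq_len(n))

#' Generate synthetic co-fractionation profile matrices
#'
#' Builds one protein-by-fraction SILAC-ratio matrix per replicate. A
#' protein's noise-free profile is the sum, over all assemblies it belongs
#' to, of a Gaussian elution peak of that assembly (height = the protein's
#' amplitude in that assembly, centre = assembly apex plus a small
#' per-replicate jitter, width = assembly sigma). Each measured cell is then
#' perturbed by multiplicative log-normal noise; values below the detection
#' threshold, or hit by independent Bernoulli dropout, become missing.
#' Proteins with no observed value in a replicate are absent from that
#' replicate's matrix, as an undetected protein would be.
#'
#' @param truth a [sim_truth()] object.
#' @return list of tibbles, one per replicate; each has a `protein` column
#'   followed by `fraction_1 .. fraction_N` columns, with attribute
#'   `replicate`.
#' @export
#' @examples
#' tr <- sim_truth(sim_params(n_proteins = 30, n_complexes = 4, seed = 2))
#' profs <- sim_profiles(tr)
#' dim(profs[[1]])
sim_profiles <- function(truth) {
  stopifnot(inherits(truth, "pcp_truth"))
  p <- truth$params
  with_rng(truth$streams[["profiles"]], {
    fr <- seq_len(p$n_fractions)
    lapply(seq_len(p$n_replicates), function(rep_i) {
      jit <- rnorm(nrow(truth$assemblies), 0, p$apex_jitter)
      apex <- truth$assemblies$apex + jit
      names(apex) <- truth$assemblies$assembly
      sigma <- setNames(truth$assemblies$sigma, truth$assemblies$assembly)

      proteins <- sort(unique(truth$memberships$protein))
      mat <- matrix(0, length(proteins), p$n_fractions,
                    dimnames = list(proteins, NULL))
      for (k in seq_len(nrow(truth$memberships))) {
        pr <- truth$memberships$protein[k]
        as_ <- truth$memberships$assembly[k]
        mat[pr, ] <- mat[pr, ] + truth$memberships$amplitude[k] *
          exp(-(fr - apex[as_])^2 / (2 * sigma[as_]^2))
      }
      if (p$noise_sd > 0) {
        mat <- mat * exp(matrix(rnorm(length(mat), 0, p$noise_sd), nrow(mat)))
      }
      mat[mat < p$detection_threshold] <- NA_real_
      if (p$missing_rate > 0) {
        drop <- matrix(runif(length(mat)) < p$missing_rate, nrow(mat))
        mat[drop] <- NA_real_
      }
      keep <- rowSums(!is.na(mat)) > 0
      mat <- mat[keep, , drop = FALSE]
      out <- as_tibble(mat, .name_repair = ~ fraction_cols(p$n_fractions))
      out <- dplyr::bind_cols(tibble(protein = rownames(mat)), out)
      attr(out, "replicate") <- sprintf("rep%d", rep_i)
      out
    })
  })
}

## shared latent-factor construction: co-complex pairs correlate at rho_c,
## everything else at rho_b (requires 0 <= rho_b <= rho_c <= 1)
latent_factor_matrix <- function(truth, co_complex_r, background_r,
                                 n_conditions, coverage) {
  stopifnot(abs(co_complex_r) <= 1, abs(background_r) <= 1,
            coverage >= 0, coverage <= 1)
  if (background_r < 0 || co_complex_r < background_r) {
    stop("latent-factor construction needs 0 <= background_r <= co_complex_r",
         call. = FALSE)
  }
  proteins <- sprintf("P%04d", seq_len(truth$params$n_proteins))
  g <- rnorm(n_conditions)
  z <- matrix(rnorm(n_conditions * max(1, length(truth$complexes))),
              ncol = max(1, length(truth$complexes)),
              dimnames = list(NULL, if (length(truth$complexes))
                names(truth$complexes) else "none"))
  ## first listed complex provides a moonlighter's latent factor
  home <- vapply(proteins, function(pr) {
    hit <- names(truth$complexes)[vapply(truth$complexes,
                                         function(m) pr %in% m, logical(1))]
    if (length(hit)) hit[1] else NA_character_
  }, character(1))
  w_b <- sqrt(background_r)
  w_c <- sqrt(co_complex_r - background_r)
  w_e <- sqrt(1 - co_complex_r)
  mat <- vapply(proteins, function(pr) {
    zc <- if (is.na(home[pr])) rnorm(n_conditions) else z[, home[pr]]
    w_b * g + w_c * zc + w_e * rnorm(n_conditions)
  }, numeric(n_conditions))
  mat <- t(mat)
  colnames(mat) <- sprintf("cond_%d", seq_len(n_conditions))
  if (coverage < 1) {
    keep <- sort(sample(proteins, round(coverage * length(proteins))))
    mat <- mat[keep, , drop = FALSE]
  }
  out <- as_tibble(mat)
  dplyr::bind_cols(tibble(protein = rownames(mat)), out)
}

#' Generate a synthetic co-expression matrix
#'
#' Stand-in for an external expression-compendium feature: proteins receive
#' condition vectors built from shared latent factors so that co-complex
#' pairs have expected Pearson correlation `co_complex_r` and all other
#' pairs `background_r`. A random `1 - coverage` fraction of proteins is
#' omitted, so downstream feature computation must mean-impute those pairs.
#'
#' @param truth a [sim_truth()] object.
#' @param co_complex_r,background_r target Pearson correlations
#'   (`0 <= background_r <= co_complex_r <= 1`).
#' @param n_conditions number of expression conditions.
#' @param coverage fraction of proteins present in the matrix.
#' @return tibble `protein`, `cond_1 .. cond_n`.
#' @export
sim_coexpression <- function(truth, co_complex_r = 0.7, background_r = 0.1,
                             n_conditions = 200, coverage = 0.9) {
  stopifnot(inherits(truth, "pcp_truth"))
  with_rng(truth$streams[["coexpr"]],
    latent_factor_matrix(truth, co_complex_r, background_r,
                         n_conditions, coverage))
}

#' Generate a synthetic phenotype matrix
#'
#' Stand-in for a stress-phenotype compendium: same latent-factor
#' construction as [sim_coexpression()] but drawn from an independent random
#' stream, so regenerating one does not perturb the other.
#'
#' @inheritParams sim_coexpression
#' @return tibble `protein`, `cond_1 .. cond_n`.
#' @export
sim_phenotypes <- function(truth, co_complex_r = 0.6, background_r = 0,
                           n_conditions = 40, coverage = 0.9) {
  stopifnot(inherits(truth, "pcp_truth"))
  with_rng(truth$streams[["pheno"]],
    latent_factor_matrix(truth, co_complex_r, background_r,
                         n_conditions, coverage))
}

#' Generate synthetic annotation maps
#'
#' Emits a "GO-like" and a "domain-like" protein-to-term map. With
#' probability `co_complex_enrichment` a term seeds on a whole complex (all
#' members annotated) and is padded with random proteins up to its drawn
#' size; otherwise it annotates randomly chosen proteins. Term sizes are
#' drawn uniformly from `term_size_range`, whose default respects the
#' downstream active-term filter (terms annotating more than 20 and fewer
#' than 1000 proteins).
#'
#' @param truth a [sim_truth()] object.
#' @param n_terms terms per map.
#' @param term_size_range inclusive integer range of term sizes.
#' @param co_complex_enrichment probability a term is complex-seeded.
#' @return list of two tibbles (`go`, `domain`), each `protein`, `term`.
#' @export
sim_annotations <- function(truth, n_terms = 50, term_size_range = c(21, 30),
                            co_complex_enrichment = 0.5) {
  stopifnot(inherits(truth, "pcp_truth"), all(term_size_range > 0),
            co_complex_enrichment >= 0, co_complex_enrichment <= 1)
  proteins <- sprintf("P%04d", seq_len(truth$params$n_proteins))
  term_size_range[2] <- min(term_size_range[2], length(proteins))
  one_map <- function(prefix) {
    size_choices <- seq(term_size_range[1], term_size_range[2])
    purrr::map_dfr(seq_len(n_terms), function(i) {
      size <- size_choices[sample.int(length(size_choices), 1)]
      members <- character(0)
      if (length(truth$complexes) && runif(1) < co_complex_enrichment) {
        ## a complex-seeded term annotates one whole complex and is padded
        ## with random proteins up to its drawn size
        ci <- sample.int(length(truth$complexes), 1)
        members <- unique(truth$complexes[[ci]])
      }
      pad <- setdiff(proteins, members)
      extra <- sample(pad, max(0, size - length(members)))
      tibble(protein = sort(unique(c(members, extra))),
             term = sprintf("%s%03d", prefix, i))
    })
  }
  with_rng(truth$streams[["annot"]],
    list(go = one_map("GO"), domain = one_map("DOM")))
}

#' Generate a partially known gold standard from the truth
#'
#' Retains a random subset of the true complexes, simulating the partial
#' knowledge of curated complex databases; it never invents false
#' complexes, so every "interacting" pair label it induces is a true
#' co-complex pair.
#'
#' @param truth a [sim_truth()] object.
#' @param known_fraction fraction of true complexes retained, in (0, 1].
#' @return tibble `complex`, `protein` (class `pcp_gold`).
#' @export
sim_gold_standard <- function(truth, known_fraction = 0.6) {
  stopifnot(inherits(truth, "pcp_truth"),
            known_fraction > 0, known_fraction <= 1)
  with_rng(truth$streams[["gold"]], {
    k <- round(known_fraction * length(truth$complexes))
    keep <- sort(sample(names(truth$complexes), k))
    gold_standard(truth$complexes[keep])
  })
}

#' Construct a gold standard from a list of complexes
#'
#' @param complexes named list of protein-id character vectors.
#' @return tibble `complex`, `protein` with class `pcp_gold`.
#' @export
gold_standard <- function(complexes) {
  stopifnot(is.list(complexes))
  if (is.null(names(complexes)) && length(complexes)) {
    names(complexes) <- sprintf("G%03d", seq_along(complexes))
  }
  out <- purrr::imap_dfr(complexes,
                         ~ tibble(complex = .y, protein = unique(.x)))
  if (!nrow(out)) out <- tibble(complex = character(), protein = character())
  structure(out, class = c("pcp_gold", class(out)))
}

## named list of member vectors from a pcp_gold tibble
gold_complex_list <- function(gold) {
  split(gold$protein, gold$complex)
}

#' Generate a synthetic external interactome
#'
#' Stand-in for an independently collected validating interactome: samples
#' true co-complex pairs at a given recall and adds random false pairs.
#'
#' @param truth a [sim_truth()] object.
#' @param true_edge_recall fraction of true pairs included.
#' @param false_edge_count number of random non-co-complex pairs added.
#' @param seed optional stream override; defaults to the truth's
#'   `external` stream.
#' @return tibble of canonical pairs `protein_a`, `protein_b`.
#' @export
sim_external_interactome <- function(truth, true_edge_recall = 0.5,
                                     false_edge_count = 200, seed = NULL) {
  stopifnot(inherits(truth, "pcp_truth"),
            true_edge_recall >= 0, true_edge_recall <= 1)
  seed <- seed %||% truth$streams[["external"]]
  with_rng(seed, {
    tp <- true_pairs(truth)
    take <- round(true_edge_recall * nrow(tp))
    picked <- tp[sort(sample(nrow(tp), take)), ]
    proteins <- sprintf("P%04d", seq_len(truth$params$n_proteins))
    false_edges <- tibble(protein_a = character(), protein_b = character())
    if (false_edge_count > 0) {
      universe <- all_pairs(proteins) %>%
        anti_join(tp, by = c("protein_a", "protein_b"))
      if (false_edge_count > nrow(universe)) {
        stop("false_edge_count exceeds the number of available non-true pairs",
             call. = FALSE)
      }
      false_edges <- universe[sort(sample(nrow(universe), false_edge_count)), ]
    }
    bind_rows(picked, false_edges) %>%
      arrange(.data$protein_a, .data$protein_b)
  })
}
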