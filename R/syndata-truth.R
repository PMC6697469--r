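#' Generate the ground truth of a synthetic co-fractionation experiment
#'
#' Samples the latent structure every other generator conditions on: which
#' proteins form complexes, which are monomeric, which moonlight in more
#' than one complex, and where each assembly elutes (its apex fraction,
#' obtained by passing a sampled assembly mass through the SEC calibration)
#' and how wide its elution peak is.
#'
#' @param params a [sim_params()] object.
#' @return an object of class `pcp_truth`: a list with
#'   \describe{
#'     \item{complexes}{named list of protein-id character vectors,}
#'     \item{monomers}{character vector of monomeric protein ids,}
#'     \item{assemblies}{tibble of assembly, mass (kDa), apex (fractions),
#'       sigma (fractions) — one row per complex and per monomer,}
#'     \item{memberships}{tibble of protein, assembly, amplitude,}
#'     \item{moonlighters}{named list protein -> complexes (only proteins in
#'       more than one complex),}
#'     \item{params}{the generating parameters.}
#'   }
#' @export
#' @examples
#' tr <- sim_truth(sim_params(n_proteins = 40, n_complexes = 5, seed = 1))
#' length(tr$complexes)
sim_truth <- function(params) {
  validate_params(params)
  streams <- seed_streams(params$seed, c("truth", "profiles", "coexpr",
                                         "annot", "pheno", "gold", "external"))
  with_rng(streams[["truth"]], {
    n <- params$n_proteins
    proteins <- sprintf("P%04d", seq_len(n))
    masses <- setNames(
      exp(rnorm(n, params$mass_meanlog, params$mass_sdlog)), proteins)

    complexes <- list()
    if (params$n_complexes > 0) {
      size_choices <- seq(params$complex_size_range[1],
                          params$complex_size_range[2])
      sizes <- size_choices[sample.int(length(size_choices),
                                       params$n_complexes, replace = TRUE)]
      capacity <- if (is.null(params$monomer_fraction)) n else
        floor(n * (1 - params$monomer_fraction))
      if (sum(sizes) > capacity) {
        stop("infeasible complex size distribution: ", sum(sizes),
             " memberships drawn but only ", capacity,
             " proteins available for complexes", call. = FALSE)
      }
      pool <- sample(proteins)[seq_len(sum(sizes))]
      complexes <- setNames(
        split(pool, rep(seq_along(sizes), sizes)),
        sprintf("C%03d", seq_along(sizes)))
    }

    ## moonlighting: a member may join one additional, different complex
    if (params$moonlight_rate > 0 && length(complexes) > 1) {
      members <- unique(unlist(complexes))
      lucky <- members[runif(length(members)) < params$moonlight_rate]
      for (pr in lucky) {
        home <- names(complexes)[vapply(complexes, function(m) pr %in% m,
                                        logical(1))]
        other <- setdiff(names(complexes), home)
        if (length(other)) {
          pick <- sample(other, 1)
          complexes[[pick]] <- c(complexes[[pick]], pr)
        }
      }
    }

    in_complex <- unique(unlist(complexes))
    monomers <- setdiff(proteins, in_complex)

    cx_mass <- vapply(complexes, function(m) sum(masses[m]), numeric(1))
    assemblies <- tibble(
      assembly = c(names(complexes), monomers),
      mass = c(unname(cx_mass), unname(masses[monomers]))
    )
    assemblies$apex <- mass_to_apex(assemblies$mass, params)
    assemblies$sigma <- runif(nrow(assemblies), params$sigma_range[1],
                              params$sigma_range[2])

    memberships <- bind_rows(
      purrr::imap_dfr(complexes,
                      function(m, nm) tibble(protein = m, assembly = nm)),
      tibble(protein = monomers, assembly = monomers)
    )
    memberships$amplitude <- exp(rnorm(nrow(memberships),
                                       params$amplitude_meanlog,
                                       params$amplitude_sdlog))

    counts <- table(unlist(lapply(complexes, unique)))
    moon <- names(counts)[counts > 1]
    moonlighters <- lapply(setNames(moon, moon), function(pr)
      names(complexes)[vapply(complexes, function(m) pr %in% m, logical(1))])

    structure(
      list(complexes = complexes, monomers = monomers,
           assemblies = assemblies, memberships = memberships,
           moonlighters = moonlighters, params = params,
           streams = streams),
      class = "pcp_truth")
  })
}

#' @export
print.pcp_truth <- function(x, ...) {
  cat("<pcp_truth> ", x$params$n_proteins, " proteins: ",
      length(x$complexes), " complexes, ", length(x$monomers),
      " monomers, ", length(x$moonlighters), " moonlighters; ",
      nrow(true_pairs(x)), " true co-complex pairs\n", sep = "")
  invisible(x)
}

#' True co-complex protein pairs of a synthetic truth
#'
#' @param truth a [sim_truth()] object.
#' @return tibble of canonical unordered pairs (`protein_a < protein_b`),
#'   one row per distinct pair that shares at least one complex.
#' @export
true_pairs <- function(truth) {
  stopifnot(inherits(truth, "pcp_truth"))
  if (!length(truth$complexes)) {
    return(tibble(protein_a = character(), protein_b = character()))
  }
  purrr::map_dfr(truth$complexes, function(m) all_pairs(unique(m))) %>%
    distinct(.data$protein_a, .data$protein_b) %>%
    arrange(.data$protein_a, .data$protein_b)
}
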