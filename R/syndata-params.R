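#' Parameters for the synthetic co-fractionation generator
#'
#' Bundles every tunable of the synthetic experiment: how many proteins and
#' complexes exist, how they elute, how noisy and how incomplete the
#' measurement is, and the SEC column calibration that maps assembly mass to
#' an elution fraction.
#'
#' Defaults describe a desk-scale experiment in the style of a SILAC-labelled
#' membrane-protein library fractionated over 54 SEC fractions in two
#' biological replicates: 150 proteins, 25 planted complexes of 3-6 subunits
#' (median size close to the five-subunit median reported for bacterial
#' membrane complex censuses), moderate multiplicative log-normal ratio noise
#' and a small stochastic dropout rate on top of detection-limit censoring.
#'
#' @param n_proteins number of proteins in the simulated proteome.
#' @param n_complexes number of planted complexes.
#' @param complex_size_range integer range `c(min, max)`; complex sizes are
#'   drawn uniformly from this range (min must be >= 2).
#' @param n_fractions number of SEC fractions (default 54).
#' @param n_replicates number of biological replicates (default 2).
#' @param noise_sd standard deviation, on the natural-log scale, of the
#'   multiplicative noise applied to each measured intensity. SILAC ratios
#'   are positive and ratio-scaled, so noise is modelled as
#'   `value * exp(rnorm(0, noise_sd))`.
#' @param missing_rate independent Bernoulli dropout probability per cell.
#' @param detection_threshold intensities below this value are censored to
#'   missing (detection limit).
#' @param monomer_fraction optional fraction of proteins reserved as
#'   monomers. `NULL` (default) means every protein not drawn into a complex
#'   is monomeric. When given, at most `floor(n_proteins * (1 -
#'   monomer_fraction))` proteins may be complex members and an infeasible
#'   size draw is an error.
#' @param moonlight_rate probability that a complex member also joins a
#'   second, randomly chosen complex (moonlighting).
#' @param apex_jitter per-replicate standard deviation (in fractions) of the
#'   random shift applied to each assembly's elution apex; emulates
#'   replicate-to-replicate chromatographic drift (default 0.25, i.e. well
#'   under half a fraction).
#' @param sigma_range range of Gaussian elution-peak widths (fractions).
#' @param amplitude_meanlog,amplitude_sdlog log-normal parameters of the
#'   peak height assigned to each protein-in-assembly.
#' @param mass_meanlog,mass_sdlog log-normal parameters (kDa) of individual
#'   protein masses; an assembly's mass is the sum of its members' masses.
#' @param calibration SEC calibration: list with `void_volume` and
#'   `total_volume` (mL; defaults 6 and 18) and `mass_range = c(low, high)`,
#'   the masses (kDa) eluting at the total and void volume respectively.
#'   Elution volume is linear in log10(mass) between the two, fractions are
#'   evenly spaced between void and total volume, and larger assemblies
#'   elute in earlier fractions. The default range brackets the simulated
#'   monomer and assembly masses, as a column is chosen to resolve its
#'   sample across the fractionation range.
#' @param seed integer seed; every downstream generator derives its own
#'   independent stream from it.
#'
#' @return an object of class `pcp_params` (a validated named list).
#' @export
#' @examples
#' p <- sim_params(n_proteins = 40, n_complexes = 6, seed = 7)
#' names(p)
sim_params <- function(n_proteins = 150,
                       n_complexes = 25,
                       complex_size_range = c(3L, 6L),
                       n_fractions = 54L,
                       n_replicates = 2L,
                       noise_sd = 0.35,
                       missing_rate = 0.05,
                       detection_threshold = 0.1,
                       monomer_fraction = NULL,
                       moonlight_rate = 0.05,
                       apex_jitter = 0.25,
                       sigma_range = c(1.5, 3),
                       amplitude_meanlog = log(10),
                       amplitude_sdlog = 0.4,
                       mass_meanlog = log(35),
                       mass_sdlog = 0.7,
                       calibration = list(void_volume = 6, total_volume = 18,
                                          mass_range = c(15, 600)),
                       seed = 1L) {
  p <- list(
    n_proteins = as.integer(n_proteins), n_complexes = as.integer(n_complexes),
    complex_size_range = as.integer(complex_size_range),
    n_fractions = as.integer(n_fractions), n_replicates = as.integer(n_replicates),
    noise_sd = noise_sd, missing_rate = missing_rate,
    detection_threshold = detection_threshold,
    monomer_fraction = monomer_fraction, moonlight_rate = moonlight_rate,
    apex_jitter = apex_jitter, sigma_range = sigma_range,
    amplitude_meanlog = amplitude_meanlog, amplitude_sdlog = amplitude_sdlog,
    mass_meanlog = mass_meanlog, mass_sdlog = mass_sdlog,
    calibration = calibration, seed = as.integer(seed)
  )
  validate_params(p)
  structure(p, class = "pcp_params")
}

validate_params <- function(p) {
  stopifnot(
    p$n_proteins >= 1, p$n_complexes >= 0, p$n_fractions >= 2,
    p$n_replicates >= 1,
    length(p$complex_size_range) == 2, p$complex_size_range[1] >= 2,
    diff(p$complex_size_range) >= 0,
    p$noise_sd >= 0, p$missing_rate >= 0, p$missing_rate <= 1,
    p$detection_threshold >= 0,
    p$moonlight_rate >= 0, p$moonlight_rate <= 1,
    p$apex_jitter >= 0, all(p$sigma_range > 0),
    p$calibration$void_volume < p$calibration$total_volume,
    length(p$calibration$mass_range) == 2,
    diff(p$calibration$mass_range) > 0
  )
  if (!is.null(p$monomer_fraction)) {
    stopifnot(p$monomer_fraction >= 0, p$monomer_fraction <= 1)
  }
  invisible(p)
}

#' @export
print.pcp_params <- function(x, ...) {
  cat("<pcp_params> ", x$n_proteins, " proteins, ", x$n_complexes,
      " complexes, ", x$n_fractions, " fractions x ", x$n_replicates,
      " replicates, noise_sd = ", x$noise_sd, ", seed = ", x$seed, "\n",
      sep = "")
  invisible(x)
}

## map assembly mass (kDa) to a fractional elution position in
## [1, n_fractions]; linear in log10(mass) between the column's void and
## total volume, largest mass earliest
mass_to_apex <- function(mass, params) {
  lr <- log10(params$calibration$mass_range)
  lm <- pmin(pmax(log10(mass), lr[1]), lr[2])
  1 + (lr[2] - lm) / (lr[2] - lr[1]) * (params$n_fractions - 1)
}
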