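# Evolutionary quantities derived from the fitted DFE parameters.
#
# Conventions: the mutational variance uses the SD of single-mutation
# effects only, V_m = rate * sigma^2, with the spontaneous per-generation
# diploid genomic mutation rate for biomass/fitness (default 0.16); the
# environmental variance is the residual noise variance, V_e = eta^2.
# All rounding conventions are explicit arguments, never silent.

#' Per-generation mutational variance
#'
#' `V_m = rate * sigma^2`: new genetic variance per generation contributed by
#' spontaneous mutation, extrapolated from the induced-mutation estimate of
#' the single-mutation effect SD.
#'
#' @param sigma SD of single-mutation fitness effects (log10 mg, >= 0).
#' @param rate_per_generation expected spontaneous mutations affecting the
#'   trait per diploid genome per generation (default 0.16).
#' @return `V_m` in (log10 mg)^2 per generation.
#' @export
mutational_variance <- function(sigma, rate_per_generation = 0.16) {
  stopifnot(sigma >= 0, rate_per_generation > 0)
  rate_per_generation * sigma^2
}

#' Per-generation mutational heritability
#'
#' `h2_m = rate * sigma^2 / eta^2`, with `V_e = eta^2` the residual noise
#' variance.
#'
#' @inheritParams mutational_variance
#' @param eta residual noise SD (log10 mg, > 0).
#' @param rate expected trait mutations per diploid genome per generation.
#' @return Dimensionless per-generation heritability increment.
#' @export
mutational_heritability <- function(sigma, eta, rate = 0.16) {
  if (length(eta) != 1 || !is.finite(eta) || eta <= 0)
    stop("eta must be a single positive number", call. = FALSE)
  stopifnot(sigma >= 0, rate > 0)
  rate * sigma^2 / eta^2
}

#' Genetic variance among founder accessions
#'
#' Sample variance (n - 1 denominator) of founder genetic values.
#'
#' @param values numeric vector of genetic values (>= 2 values).
#' @return `V_g` in (log10 mg)^2.
#' @export
genetic_variance_across_founders <- function(values) {
  if (length(values) < 2)
    stop("need at least two genetic values", call. = FALSE)
  stats::var(values)
}

#' Generations for mutation alone to build a target heritability
#'
#' `target_h2 / h2m`, optionally rounded.
#'
#' @param target_h2 target heritability in (0, 1).
#' @param h2m per-generation mutational heritability (> 0).
#' @param round_to round the generation count to the nearest multiple of
#'   this value (default 1, i.e. nearest generation); use `NULL` for the
#'   raw quotient.
#' @return Number of generations.
#' @export
generations_to_target_h2 <- function(target_h2, h2m, round_to = 1) {
  if (!is.finite(h2m) || h2m <= 0)
    stop("h2m must be positive", call. = FALSE)
  stopifnot(target_h2 > 0, target_h2 < 1)
  out <- target_h2 / h2m
  if (is.null(round_to)) out else max(round_to, round(out / round_to) * round_to)
}

#' Generations for a low-fitness lineage to reach a high-fitness one
#'
#' Assuming a zero-mean DFE with constant variance, the mutational variance
#' accumulated over `t` generations is `t * V_m`; the number of generations
#' until the fitness distribution of the low lineage contains the high
#' lineage's genetic value within 2 SDs is `(y_high - y_low)^2 / (4 * V_m)`.
#'
#' @param y_high,y_low genetic values (log10 mg) of the better- and
#'   worse-adapted lineages.
#' @param v_m_low per-generation mutational variance of the low lineage
#'   (> 0).
#' @return Number of generations (unrounded).
#' @export
generations_to_overlap <- function(y_high, y_low, v_m_low) {
  if (!is.finite(v_m_low) || v_m_low <= 0)
    stop("v_m_low must be positive", call. = FALSE)
  (y_high - y_low)^2 / (4 * v_m_low)
}

#' Ratio of standing genetic variance to mutational variance
#'
#' @param v_g among-accession genetic variance.
#' @param v_m per-generation mutational variance (> 0).
#' @return `v_g / v_m`, the number of generations of mutational input the
#'   standing variance represents.
#' @export
vg_to_vm_ratio <- function(v_g, v_m) {
  if (!is.finite(v_m) || v_m <= 0)
    stop("v_m must be positive", call. = FALSE)
  v_g / v_m
}

#' Fraction of the spontaneous mutation spectrum covered by EMS
#'
#' EMS induces single-nucleotide substitutions but no indels, so it samples
#' `snm / (snm + indel)` of the spontaneous spectrum.
#'
#' @param snm_rate spontaneous single-nucleotide mutation rate per site per
#'   generation (default 7e-9).
#' @param indel_rate spontaneous indel rate (default 1.3e-9).
#' @return Percentage in (0, 100].
#' @export
ems_spectrum_fraction <- function(snm_rate = 7e-9, indel_rate = 1.3e-9) {
  stopifnot(snm_rate > 0, indel_rate >= 0)
  100 * snm_rate / (snm_rate + indel_rate)
}

#' Proportion of mutations homozygous after selfing
#'
#' After `g` generations of selfing from a heterozygous carrier, the
#' probability that a surviving mutation is no longer segregating is
#' `1 - (1/2)^g` (computed here by exact chain enumeration).
#'
#' @param g selfing generations.
#' @return Percentage of mutations fixed or lost (homozygous either way).
#' @export
selfing_homozygosity <- function(g) {
  p <- dosage_moments(g)$distribution
  100 * (p[["0"]] + p[["2"]])
}

#' Full derived-quantity report from fitted parameters
#'
#' Computes, per focal founder, the mutational variance and heritability,
#' and across founders the genetic variance, the generations needed for
#' mutation alone to build a target heritability (from the mean mutational
#' heritability), pairwise Vg/Vm ratios, and the generations-to-overlap
#' extrapolation from the lowest to the highest focal genetic value.
#'
#' @param y named numeric vector of founder genetic values (log10 mg).
#' @param sigma named numeric vector of DFE SDs for the focal founders.
#' @param eta named numeric vector of residual SDs (at least the focal
#'   founders).
#' @param rate spontaneous trait-mutation rate per generation.
#' @param target_h2 target heritability for the generation extrapolation.
#' @return List with elements `per_founder` (data frame: founder, sigma,
#'   eta, v_m, h2_m), `v_g`, `mean_h2m`, `generations_to_target_h2`,
#'   `vg_to_vm`, and `generations_to_overlap` (NULL with fewer than two
#'   focal founders).
#' @export
derived_report <- function(y, sigma, eta, rate = 0.16, target_h2 = 0.5) {
  stopifnot(length(y) >= 2, length(sigma) >= 1,
            !is.null(names(sigma)), !is.null(names(y)))
  focal <- names(sigma)
  stopifnot(all(focal %in% names(eta)))
  v_m <- vapply(focal, function(f) mutational_variance(sigma[[f]], rate),
                numeric(1))
  h2 <- vapply(focal, function(f)
    mutational_heritability(sigma[[f]], eta[[f]], rate), numeric(1))
  v_g <- genetic_variance_across_founders(unname(y))
  overlap <- NULL
  if (length(focal) >= 2) {
    yf <- y[focal]
    lo <- focal[which.min(yf)]; hi <- focal[which.max(yf)]
    overlap <- list(
      low = lo, high = hi,
      generations = generations_to_overlap(y[[hi]], y[[lo]], v_m[[lo]])
    )
  }
  list(
    per_founder = data.frame(founder = focal, sigma = unname(sigma[focal]),
                             eta = unname(eta[focal]), v_m = unname(v_m),
                             h2_m = unname(h2), stringsAsFactors = FALSE),
    v_g = v_g,
    mean_h2m = mean(h2),
    generations_to_target_h2 =
      generations_to_target_h2(target_h2, mean(h2), round_to = 100),
    vg_to_vm = vapply(focal, function(f) vg_to_vm_ratio(v_g, v_m[[f]]),
                      numeric(1)),
    generations_to_overlap = overlap
  )
}
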