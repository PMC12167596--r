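# Generative simulator of the mutagenesis field experiment.
#
# Breeding design emulated: a single founder plant per accession is (for the
# two focal accessions) mutagenized, producing heterozygous M1 plants that
# self for one generation to M2 (one M2 genotype per line), are split into
# two sublines at M3, and self once more so the plants scored in the field
# are M4.  Each line carries P ~ Poisson(lambda) mutations whose allele
# dosage segregates down this pedigree; a plant's mutational deviation is
# h = sum n_m e_m.  Phenotype model: genetic value s = y + m + h + b on the
# log10-mg scale (maternal effect m per subline, block effect b per field
# block); survival is Bernoulli with p = 1 / (1 + exp(c*s + d)); survivors
# get dry weight 10^(s + eps) with eps ~ Normal(0, eta^2).

#' Logistic survival probability
#'
#' Survival probability of a plant with genetic value `s` (log10 mg):
#' `p = 1 / (1 + exp(c * s + d))`.  With `c < 0` higher genetic value gives
#' higher survival; `c = d = 0` gives probability exactly 1/2.
#'
#' @param s genetic value(s), log10 mg.
#' @param c,d logistic shape parameters.
#' @return Numeric vector of probabilities.
#' @export
survival_prob <- function(s, c, d) {
  stats::plogis(-(c * s + d))
}

#' Default founder panel of the simulated experiment
#'
#' Six accessions: two focal founders with EMS mutant lines (20 and 16
#' lines) plus 120-plant controls, and four reference accessions with
#' 120-plant controls only.  Genetic values and residual-noise SDs are the
#' study-condition defaults of the simulator.
#'
#' @return Data frame with columns `founder_id`, `y` (genetic value, log10
#'   mg), `n_ems_lines`, `n_control_plants`, `eta` (residual SD, log10 mg).
#' @export
default_founders <- function() {
  data.frame(
    founder_id = c("COL", "CV", "28051", "28364", "28510", "76197"),
    y = c(2.886, 2.164, 2.298, 3.125, 3.109, 2.941),
    n_ems_lines = c(20L, 16L, 0L, 0L, 0L, 0L),
    n_control_plants = 120L,
    eta = c(0.208, 0.327, 0.762, 0.074, 0.218, 0.215),
    stringsAsFactors = FALSE
  )
}

#' Full generative specification of a simulated experiment
#'
#' Defaults reproduce the field design: 6 founders, 20 + 16 EMS lines of
#' 2 sublines x 60 plants for the focal founders, 120 control plants per
#' founder (2 sublines x 60), 12 blocks, Poisson(25) mutations per line,
#' three selfing generations with the subline split after the first.  The
#' default DFEs are normal with the focal founders' estimated moments, the
#' logistic survival parameters are calibrated so the two focal controls
#' survive at rates approximately 0.51 and 0.35, and maternal/block effect
#' SDs default to 0.02 log10 mg (small nuisance scales; block point
#' estimates in the field data scatter with SD about 0.02).
#'
#' @param founders founder panel as from [default_founders()].
#' @param dfe named list of [dfe_spec()]s, one per founder with EMS lines.
#' @param lambda_mut mean mutations per EMS line (default 25).
#' @param n_sublines sublines per EMS line (default 2).
#' @param n_per_subline plants per subline (default 60).
#' @param n_control_sublines sublines the control plants are split into
#'   (default 2).
#' @param n_blocks number of field blocks (default 12).
#' @param maternal_sd,block_sd SD of subline maternal and block effects
#'   (log10 mg).
#' @param noise_sd optional scalar residual SD overriding the per-founder
#'   `eta` column (`NULL` to use the panel values).
#' @param survival_c,survival_d logistic survival parameters.
#' @param selfing_generations selfing generations from mutagenized plant to
#'   measured plants (default 3; must be >= 2 so the subline split exists).
#' @param block_assignment `"round_robin"` (deterministic interleaving) or
#'   `"random"`.
#' @param seed master RNG seed.
#' @return Object of class `simulation_config` (a list).
#' @export
simulation_config <- function(founders = default_founders(),
                              dfe = list(
                                COL = dfe_spec("normal", mean = 0.001, sd = 0.011),
                                CV = dfe_spec("normal", mean = 0.004, sd = 0.015)
                              ),
                              lambda_mut = 25,
                              n_sublines = 2,
                              n_per_subline = 60,
                              n_control_sublines = 2,
                              n_blocks = 12,
                              maternal_sd = 0.02,
                              block_sd = 0.02,
                              noise_sd = NULL,
                              survival_c = -0.9128,
                              survival_d = 2.5943,
                              selfing_generations = 3,
                              block_assignment = c("round_robin", "random"),
                              seed = 1L) {
  block_assignment <- match.arg(block_assignment)
  stopifnot(is.data.frame(founders),
            all(c("founder_id", "y", "n_ems_lines", "n_control_plants",
                  "eta") %in% names(founders)),
            lambda_mut > 0, n_sublines >= 1, n_per_subline >= 1,
            n_control_sublines >= 1, n_blocks >= 1,
            maternal_sd >= 0, block_sd >= 0,
            selfing_generations >= 2)
  if (!is.null(noise_sd)) {
    stopifnot(noise_sd > 0)
    founders$eta <- noise_sd
  }
  stopifnot(all(founders$eta > 0))
  focal <- founders$founder_id[founders$n_ems_lines > 0]
  missing_dfe <- setdiff(focal, names(dfe))
  if (length(missing_dfe))
    stop("no dfe_spec given for EMS founder(s): ",
         paste(missing_dfe, collapse = ", "), call. = FALSE)
  structure(list(
    founders = founders, dfe = dfe, lambda_mut = lambda_mut,
    n_sublines = n_sublines, n_per_subline = n_per_subline,
    n_control_sublines = n_control_sublines, n_blocks = n_blocks,
    maternal_sd = maternal_sd, block_sd = block_sd,
    survival_c = survival_c, survival_d = survival_d,
    selfing_generations = selfing_generations,
    block_assignment = block_assignment,
    seed = as.integer(seed)
  ), class = "simulation_config")
}

#' Read a simulation configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [simulation_config()]; `founders`
#' is a list of records with `founder_id`, `y`, `n_ems_lines`,
#' `n_control_plants`, `eta`; `dfe` is a named map of
#' `{family: ..., <parameters>}` records.
#'
#' @param path YAML file path.
#' @return A [simulation_config()].
#' @export
read_simulation_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- raw
  if (!is.null(raw$founders))
    args$founders <- do.call(rbind, lapply(raw$founders, function(rec) {
      # YAML 1.1 reads a bare key `y` as boolean TRUE; map it back
      names(rec)[names(rec) == "TRUE"] <- "y"
      as.data.frame(rec)
    }))
  if (!is.null(raw$dfe))
    args$dfe <- lapply(raw$dfe, function(d) do.call(dfe_spec, d))
  do.call(simulation_config, args)
}

# simulate one EMS line (all sublines); returns a data.frame of plant rows.
# blocks/block effects are supplied by the caller so they are shared across
# the whole experiment.
.simulate_line_rows <- function(founder_id, y, eta, line_id, config,
                                block_ids, block_eff) {
  S <- config$n_sublines
  npp <- config$n_per_subline
  g <- config$selfing_generations
  dfe <- config$dfe[[founder_id]]
  P <- stats::rpois(1, config$lambda_mut)
  e <- sample_dfe(dfe, P)
  d_line <- .dosage_step(rep(1L, P))            # shared M2 genotype
  rows <- vector("list", S)
  for (s in seq_len(S)) {
    d_sub <- .dosage_step(d_line)               # subline M3 genotype
    m <- stats::rnorm(1, 0, config$maternal_sd)
    h <- numeric(npp)
    for (i in seq_len(npp)) {
      d <- d_sub
      for (gg in seq_len(g - 2)) d <- .dosage_step(d)
      h[i] <- sum(d * e)
    }
    idx <- seq_len(npp)
    bl <- block_ids[[paste(line_id, s)]]
    sval <- y + m + h + block_eff[bl]
    p <- survival_prob(sval, config$survival_c, config$survival_d)
    surv <- stats::runif(npp) < p
    w <- numeric(npp)
    w[surv] <- 10^(sval[surv] + stats::rnorm(sum(surv), 0, eta))
    rows[[s]] <- data.frame(
      founder_id = founder_id, line_id = line_id,
      subline_id = as.character(s), block_id = as.character(bl),
      ems_treated = TRUE, survived = surv, dry_weight_mg = w,
      h = h, maternal = m, block_effect = block_eff[bl],
      genetic_value = sval, stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}

.simulate_control_rows <- function(founder_id, y, eta, config,
                                   block_ids, block_eff) {
  fr <- config$founders[config$founders$founder_id == founder_id, ]
  n <- fr$n_control_plants
  S <- config$n_control_sublines
  per <- diff(round(seq(0, n, length.out = S + 1)))
  rows <- vector("list", S)
  for (s in seq_len(S)) {
    npp <- per[s]
    if (npp == 0) next
    m <- stats::rnorm(1, 0, config$maternal_sd)
    bl <- block_ids[[paste(founder_id, "control", s)]][seq_len(npp)]
    sval <- y + m + block_eff[bl]
    p <- survival_prob(sval, config$survival_c, config$survival_d)
    surv <- stats::runif(npp) < p
    w <- numeric(npp)
    w[surv] <- 10^(sval[surv] + stats::rnorm(sum(surv), 0, eta))
    rows[[s]] <- data.frame(
      founder_id = founder_id, line_id = "control",
      subline_id = as.character(s), block_id = as.character(bl),
      ems_treated = FALSE, survived = surv, dry_weight_mg = w,
      h = 0, maternal = m, block_effect = block_eff[bl],
      genetic_value = sval, stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}

#' Simulate a complete mutagenesis field experiment
#'
#' Deterministic given `config$seed`.  Control plants of every founder and
#' EMS lines of the focal founders are generated, blocks are assigned
#' round-robin (or at random) across the planting order, and one zero-mean
#' normal block effect per block is drawn once per run.
#'
#' @param config a [simulation_config()].
#' @param keep_latent if `TRUE`, keep the latent truth columns `h`,
#'   `maternal`, `block_effect`, `genetic_value` alongside the observables
#'   (useful for oracle tests); default drops them.
#' @return An [experiment_table()]; with `keep_latent = TRUE` the latent
#'   columns are attached as attribute `"latent"` (a data frame aligned row
#'   by row with the table).
#' @export
simulate_experiment <- function(config, keep_latent = FALSE) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  founders <- config$founders
  blocks <- as.character(seq_len(config$n_blocks))
  block_eff <- stats::rnorm(config$n_blocks, 0, config$block_sd)
  names(block_eff) <- blocks

  # blocks are assigned across the full planting order
  total <- sum(founders$n_control_plants) +
    sum(founders$n_ems_lines) * config$n_sublines * config$n_per_subline
  assignment <- if (config$block_assignment == "round_robin") {
    rep(blocks, length.out = total)
  } else {
    sample(rep(blocks, length.out = total))
  }
  # slice the global assignment back into per-unit block vectors; note EMS
  # unit keys are shared between the two focal founders, so slices are taken
  # founder by founder below
  pieces <- list()
  pos <- 0
  for (i in seq_len(nrow(founders))) {
    fid <- founders$founder_id[i]
    S <- config$n_control_sublines
    per <- diff(round(seq(0, founders$n_control_plants[i], length.out = S + 1)))
    fld <- list()
    for (s in seq_len(S)) {
      fld[[paste(fid, "control", s)]] <- assignment[pos + seq_len(per[s])]
      pos <- pos + per[s]
    }
    if (founders$n_ems_lines[i] > 0) {
      for (j in seq_len(founders$n_ems_lines[i]))
        for (s in seq_len(config$n_sublines)) {
          fld[[paste(paste0("L", j), s)]] <-
            assignment[pos + seq_len(config$n_per_subline)]
          pos <- pos + config$n_per_subline
        }
    }
    pieces[[fid]] <- fld
  }

  out <- vector("list", nrow(founders) * 2)
  k <- 0
  for (i in seq_len(nrow(founders))) {
    fid <- founders$founder_id[i]
    k <- k + 1
    out[[k]] <- .simulate_control_rows(fid, founders$y[i], founders$eta[i],
                                       config, pieces[[fid]], block_eff)
    if (founders$n_ems_lines[i] > 0) {
      lines <- lapply(seq_len(founders$n_ems_lines[i]), function(j)
        .simulate_line_rows(fid, founders$y[i], founders$eta[i],
                            paste0("L", j), config, pieces[[fid]], block_eff))
      k <- k + 1
      out[[k]] <- do.call(rbind, lines)
    }
  }
  df <- do.call(rbind, out[seq_len(k)])
  rownames(df) <- NULL
  latent <- df[, c("h", "maternal", "block_effect", "genetic_value")]
  tab <- experiment_table(df[, .et_columns])
  if (keep_latent) attr(tab, "latent") <- latent
  tab
}

#' Simulate a single EMS mutant line
#'
#' Convenience wrapper generating one line (all sublines) with its own block
#' assignment and block effects; mostly useful for focused tests.  For whole
#' experiments use [simulate_experiment()].
#'
#' @param founder_id founder label; must have a `dfe_spec` in `config$dfe`.
#' @param y founder genetic value (log10 mg).
#' @param eta residual SD (log10 mg).
#' @param line_id line label.
#' @param config a [simulation_config()].
#' @return An [experiment_table()] with latent columns attached as attribute
#'   `"latent"`.
#' @export
simulate_line <- function(founder_id, y, eta, line_id, config) {
  stopifnot(inherits(config, "simulation_config"))
  blocks <- as.character(seq_len(config$n_blocks))
  block_eff <- stats::rnorm(config$n_blocks, 0, config$block_sd)
  names(block_eff) <- blocks
  n <- config$n_sublines * config$n_per_subline
  bl <- rep(blocks, length.out = n)
  block_ids <- list()
  for (s in seq_len(config$n_sublines))
    block_ids[[paste(line_id, s)]] <-
      bl[(s - 1) * config$n_per_subline + seq_len(config$n_per_subline)]
  df <- .simulate_line_rows(founder_id, y, eta, line_id, config,
                            block_ids, block_eff)
  latent <- df[, c("h", "maternal", "block_effect", "genetic_value")]
  tab <- experiment_table(df[, .et_columns])
  attr(tab, "latent") <- latent
  tab
}
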