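# Small in-code fixtures shared across test files.

# four plants, two survivors with weights 100 and 1000 mg
tiny_table <- function() {
  experiment_table(data.frame(
    founder_id = "A", line_id = "control", subline_id = c("1", "1", "2", "2"),
    block_id = c("1", "2", "1", "2"), ems_treated = FALSE,
    survived = c(TRUE, FALSE, TRUE, FALSE),
    dry_weight_mg = c(100, 0, 1000, 0),
    stringsAsFactors = FALSE
  ))
}

# a compact two-founder design: founder A mutagenized, founder B control-only
small_sim_config <- function(seed = 1, n_ems_lines_A = 4L,
                             n_per_subline = 15, n_control = 60L, ...) {
  founders <- data.frame(
    founder_id = c("A", "B"),
    y = c(2.9, 2.2),
    n_ems_lines = c(n_ems_lines_A, 0L),
    n_control_plants = n_control,
    eta = c(0.2, 0.3),
    stringsAsFactors = FALSE
  )
  simulation_config(
    founders = founders,
    dfe = list(A = dfe_spec("normal", mean = 0.004, sd = 0.015)),
    n_per_subline = n_per_subline, n_blocks = 4, seed = seed, ...
  )
}

# fast variational settings for small models
small_fit_config <- function(seed = 1, ...) {
  model_config(max_iter = 2500, cov_iter = 1200, window = 100,
               n_draws = 1000, seed = seed, ...)
}

expect_within <- function(object, expected, tol) {
  expect_lt(abs(object - expected), tol)
}
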