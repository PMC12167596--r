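test_that("the default design reproduces the published per-group layout", {
  cfg <- simulation_config(seed = 1)
  tab <- simulate_experiment(cfg)
  dc <- design_counts(tab)
  get <- function(f, t, col) dc[dc$founder_id == f & dc$treatment == t, col]
  expect_equal(get("COL", "EMS", "n_lines"), 20)
  expect_equal(get("COL", "EMS", "n_seedlings"), 2400)
  expect_equal(get("CV", "EMS", "n_lines"), 16)
  expect_equal(get("CV", "EMS", "n_seedlings"), 1920)
  for (f in c("28051", "28364", "28510", "76197", "COL", "CV")) {
    expect_equal(get(f, "control", "n_lines"), 1)
    expect_equal(get(f, "control", "n_seedlings"), 120)
  }
  expect_equal(length(unique(tab$block_id)), 12)
  # every (founder, line, subline) group is populated
  counts <- table(paste(tab$founder_id, tab$line_id, tab$subline_id))
  expect_true(all(counts > 0))
})

test_that("simulation is deterministic given the seed and varies across seeds", {
  cfg <- small_sim_config(seed = 42)
  t1 <- simulate_experiment(cfg)
  t2 <- simulate_experiment(cfg)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  t3 <- simulate_experiment(small_sim_config(seed = 43))
  expect_false(identical(as.data.frame(t1), as.data.frame(t3)))
})

test_that("a point-mass-at-zero DFE leaves no mutational variation", {
  cfg <- small_sim_config(seed = 3)
  cfg$dfe$A <- dfe_spec("point_mass", value = 0)
  tab <- simulate_experiment(cfg, keep_latent = TRUE)
  lat <- attr(tab, "latent")
  expect_true(all(lat$h == 0))
  # weights still vary through maternal, block, and residual noise
  expect_gt(stats::sd(log10(tab$dry_weight_mg[tab$survived])), 0)
})

test_that("a flat logistic gives every plant survival probability one half", {
  expect_equal(survival_prob(c(-5, 0, 2.9, 10), 0, 0), rep(0.5, 4))
  # and with c < 0, survival increases with genetic value
  expect_gt(survival_prob(3, -0.9, 2.6), survival_prob(2, -0.9, 2.6))
  cfg <- small_sim_config(seed = 4, survival_c = 0, survival_d = 0,
                          n_control = 2000L)
  tab <- simulate_experiment(cfg)
  n <- sum(!tab$ems_treated)
  expect_within(mean(tab$survived[!tab$ems_treated]), 0.5, 4 * sqrt(0.25 / n))
})

test_that("the survival calibration reproduces the focal control rates", {
  founders <- default_founders()
  founders$n_control_plants <- 4000L
  founders$n_ems_lines <- 0L
  cfg <- simulation_config(founders = founders, dfe = list(), seed = 9)
  tab <- simulate_experiment(cfg)
  surv <- tapply(tab$survived, tab$founder_id, mean)
  se <- sqrt(0.25 / 4000)
  expect_within(surv[["COL"]], 0.51, 4 * se)
  expect_within(surv[["CV"]], 0.35, 4 * se)
})

test_that("latent mutational deviations match the compound-Poisson moments", {
  cfg <- small_sim_config(seed = 6, n_ems_lines_A = 150L, n_per_subline = 2)
  tab <- simulate_experiment(cfg, keep_latent = TRUE)
  lat <- attr(tab, "latent")
  ems <- tab$ems_treated
  cp <- compound_poisson_moments(25, 0.004, 0.015, g = 3)
  line_means <- tapply(lat$h[ems], tab$line_id[ems], mean)
  n_lines <- length(line_means)
  expect_equal(n_lines, 150)
  se_mean <- sqrt(cp$variance / sum(ems))
  # plant-level h is not independent within lines; bound via line count
  expect_within(mean(lat$h[ems]), cp$mean, 5 * sqrt(cp$variance / n_lines))
  expect_within(stats::var(lat$h[ems]), cp$variance,
                6 * cp$variance * sqrt(2 / n_lines))
})

test_that("one line simulation carries its latent truth and the subline split", {
  cfg <- small_sim_config(seed = 8)
  set.seed(1)
  line <- simulate_line("A", 2.9, 0.2, "L1", cfg)
  expect_equal(nrow(line), 2 * 15)
  expect_equal(sort(unique(line$subline_id)), c("1", "2"))
  lat <- attr(line, "latent")
  expect_equal(nrow(lat), nrow(line))
  # maternal effect is shared within a subline, h varies within it
  expect_equal(length(unique(lat$maternal[line$subline_id == "1"])), 1)
})
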