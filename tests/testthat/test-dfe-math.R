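test_that("dosage moments match the closed forms for a range of generations", {
  # enumeration is the implementation; the closed forms E[n] = 1 and
  # E[n^2] = 2 - 2^-g are the independent cross-check
  for (g in 1:6) {
    dm <- dosage_moments(g)
    expect_equal(dm$first_moment, 1)
    expect_equal(dm$second_moment, 2 - 2^(-g))
    expect_equal(sum(dm$distribution), 1)
    expect_equal(dm$cross_moment(g), dm$second_moment)
    expect_equal(dm$cross_moment(1:g), 2 - 2^(-(1:g)))
  }
  expect_equal(dosage_moments(1)$second_moment, 1.5)
  # all mutations eventually fix or are lost: E[n^2] -> 2
  expect_equal(dosage_moments(40)$second_moment, 2, tolerance = 1e-10)
  expect_error(dosage_moments(0), "g must be")
  expect_error(dosage_moments(1.5), "g must be")
})

test_that("Monte Carlo dosage paths agree with exact enumeration", {
  set.seed(41)
  n <- 2e5
  paths <- sample_dosage_path(3, n = n)
  expect_equal(dim(paths), c(n, 3))
  # absorbing states never change
  expect_true(all(paths[, 2][paths[, 1] == 0] == 0))
  expect_true(all(paths[, 2][paths[, 1] == 2] == 2))
  for (g in 1:3) {
    p_exact <- dosage_moments(g)$distribution
    p_emp <- tabulate(paths[, g] + 1L, 3) / n
    expect_within(p_emp[2], p_exact[["1"]], 5 * sqrt(0.25 / n))
    expect_within(mean(paths[, g]^2), dosage_moments(g)$second_moment,
                  5 * sqrt(3.7 / n))
  }
})

test_that("compound-Poisson component split is exact and conserves variance", {
  cp <- compound_poisson_moments(25, 0, 0.015, g = 3)
  expect_equal(cp$mean, 0)
  expect_equal(cp$variance, 1.875 * 25 * 0.015^2)  # 0.010546875
  expect_equal(cp$variance, 0.010546875)
  expect_equal(unname(cp$components),
               c(1.5, 0.25, 0.125) * 25 * 0.015^2)

  # conservation holds for arbitrary inputs, including degenerate ones
  set.seed(5)
  for (i in 1:25) {
    lam <- runif(1, 0.1, 60); mu <- rnorm(1, 0, 0.05)
    sg <- runif(1, 0, 0.05); g <- sample(3:6, 1)
    cp <- compound_poisson_moments(lam, mu, sg, g = g)
    expect_equal(sum(cp$components), cp$variance)
    expect_equal(cp$mean, lam * mu)
    expect_gte(min(cp$components), 0)
  }
  cp0 <- compound_poisson_moments(25, 0, 0, g = 3)
  expect_equal(cp0$variance, 0)
  expect_equal(unname(cp0$components), c(0, 0, 0))
})

test_that("the brute-force sampler reproduces the closed-form moments for every DFE family", {
  specs <- list(
    dfe_spec("point_mass", value = 0.1),
    dfe_spec("normal", mean = 0.004, sd = 0.015),
    dfe_spec("gamma_deleterious", shape = 2, scale = 0.008),
    dfe_spec("reflected_gamma", shape = 0.5, scale = 0.01),
    dfe_spec("two_component_mixture", w = 0.3, mean1 = -0.05, sd1 = 0.01,
             mean2 = 0.02, sd2 = 0.005)
  )
  set.seed(11)
  n <- 2e5
  for (spec in specs) {
    h <- sample_compound_poisson(25, spec, g = 3, n_draws = n)
    cp <- compound_poisson_moments(25, spec$mu, spec$sigma, g = 3)
    se_mean <- sqrt(cp$variance / n)
    expect_within(mean(h), cp$mean, 5 * se_mean)
    # relative tolerance on the variance: sample variance has ~sqrt(2/n)
    # relative error for normal-ish h, inflate for safety
    expect_within(stats::var(h), cp$variance, 8 * cp$variance * sqrt(2 / n))
  }
})

test_that("few expected mutations leave an atom at zero matching exact enumeration", {
  # with a point-mass DFE, h = 0 iff every mutation was lost:
  # P = exp(-lambda * P(n > 0)) with P(n = 0) = (1 - 2^-g)/2
  set.seed(13)
  lam <- 0.1
  h <- sample_compound_poisson(lam, dfe_spec("point_mass", value = 0.1),
                               g = 3, n_draws = 2e5)
  p0_exact <- exp(-lam * (1 - dosage_moments(3)$distribution[["0"]]))
  expect_equal(p0_exact, exp(-0.05625))
  expect_within(mean(h == 0), p0_exact, 5 * sqrt(p0_exact * (1 - p0_exact) / 2e5))
})

test_that("pedigree-correlated line sampler has the documented sharing structure", {
  set.seed(17)
  spec <- dfe_spec("normal", mean = 0.004, sd = 0.015)
  h <- sample_line_h(25, spec, g = 3, n_lines = 2e4,
                     n_sublines = 2, n_per_subline = 2)
  a <- 25 * (0.004^2 + 0.015^2)
  # same subline correlates more strongly than different sublines
  cov_same <- cov(h[, 1], h[, 2])
  cov_diff <- cov(h[, 1], h[, 3])
  expect_gt(cov_same, cov_diff)
  expect_within(cov_diff, 1.5 * a, 6 * sqrt((1.875^2 + 1.5^2) / 2e4) * a)
  expect_within(cov_same, 1.75 * a, 6 * sqrt((1.875^2 + 1.75^2) / 2e4) * a)
})

test_that("the normality diagnostic flags a mutation-poor skewed compound sum", {
  set.seed(19)
  skewed <- dfe_spec("gamma_deleterious", shape = 2, scale = 0.008)
  poor <- clt_diagnostic(0.5, skewed, n_draws = 4000, n_cal = 50)
  expect_false(poor$approx_ok)
  expect_gt(poor$statistic, poor$normal_q99)
  rich <- clt_diagnostic(25, dfe_spec("normal", mean = 0, sd = 0.015),
                         n_draws = 4000, n_cal = 50)
  expect_true(rich$approx_ok)
  expect_error(clt_diagnostic(25, dfe_spec("point_mass", value = 0),
                              n_draws = 1000), "degenerate")
})
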