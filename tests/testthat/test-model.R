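test_that("model assembly identifies focal founders and the latent structure", {
  tab <- simulate_experiment(small_sim_config(seed = 21))
  mod <- build_model(tab, small_fit_config())
  expect_equal(mod$focal, "A")
  expect_equal(length(mod$lines), 4)
  expect_equal(mod$n_ems, 4 * 2 * 15)
  expect_equal(length(mod$blocks), 4)
  expect_equal(unname(mod$dos_coef), c(1.5, 0.25, 0.125))

  # a control-only table builds a model without DFE parameters
  ctrl <- tab[!tab$ems_treated, ]
  mod0 <- build_model(experiment_table(ctrl), small_fit_config())
  expect_equal(length(mod0$focal), 0)

  # focal founder without control plants is flagged
  noctrl <- tab[!(tab$founder_id == "A" & !tab$ems_treated), ]
  expect_warning(build_model(experiment_table(noctrl), small_fit_config()),
                 "without control plants")
})

test_that("the analytic ELBO gradient matches finite differences", {
  tab <- simulate_experiment(small_sim_config(seed = 22, n_ems_lines_A = 2L,
                                              n_per_subline = 5,
                                              n_control = 20L))
  mod <- build_model(tab, small_fit_config())
  mod$layout <- mutdfe:::.param_layout(mod)
  set.seed(1)
  theta <- rnorm(mod$layout$D, 0, 0.3)
  theta[mod$layout$y] <- c(2.8, 2.3)
  theta[mod$layout$le] <- log(0.3)
  lg <- mutdfe:::.logp_grad(theta, mod)
  lay <- mod$layout
  probe <- c(lay$y, lay$mu, lay$ls, lay$lsm, lay$lsb, lay$le, lay$cpar,
             lay$dpar, lay$braw[1], lay$mraw[1], lay$Lraw[1], lay$Sraw[1],
             lay$Iraw[1])
  eps <- 1e-6
  for (i in probe) {
    tp <- theta; tp[i] <- tp[i] + eps
    tm <- theta; tm[i] <- tm[i] - eps
    num <- (mutdfe:::.logp_grad(tp, mod)$logp -
              mutdfe:::.logp_grad(tm, mod)$logp) / (2 * eps)
    expect_equal(lg$grad[i], num, tolerance = 1e-4)
  }
})

test_that("fits are deterministic given the seed", {
  tab <- simulate_experiment(small_sim_config(seed = 23))
  mod <- build_model(tab, small_fit_config(seed = 5))
  f1 <- suppressWarnings(fit_variational(mod))
  f2 <- suppressWarnings(fit_variational(mod))
  expect_identical(f1$summary, f2$summary)
})

test_that("posterior summaries respect positivity and credible-interval nesting", {
  tab <- simulate_experiment(small_sim_config(seed = 24))
  mod <- build_model(tab, small_fit_config(seed = 2))
  fit <- suppressWarnings(fit_variational(mod))
  sm <- fit$summary
  scales <- grepl("^(sigma|eta)\\[|_sd$", sm$parameter)
  expect_true(all(sm$mean[scales] > 0))
  expect_true(all(sm$q0.5[scales] > 0))
  pos_cols <- sm$parameter[scales]
  expect_true(all(fit$draws[, pos_cols] > 0))
  # 95% interval nested inside the 99% interval
  expect_true(all(sm$q0.5 <= sm$q2.5))
  expect_true(all(sm$q97.5 <= sm$q99.5))
})

test_that("a control-only fit recovers the direct zero-inflated estimates", {
  cfg <- small_sim_config(seed = 25, n_ems_lines_A = 0L, n_control = 400L)
  cfg$dfe <- list()
  tab <- simulate_experiment(cfg)
  mod <- build_model(tab, small_fit_config(seed = 3))
  fit <- suppressWarnings(fit_variational(mod))
  sm <- fit$summary
  for (f in c("A", "B")) {
    i <- tab$founder_id == f & tab$survived
    direct_y <- mean(log10(tab$dry_weight_mg[i]))
    direct_eta <- stats::sd(log10(tab$dry_weight_mg[i]))
    fit_y <- sm$mean[sm$parameter == paste0("y[", f, "]")]
    fit_eta <- sm$mean[sm$parameter == paste0("eta[", f, "]")]
    expect_within(fit_y, direct_y, 0.05)
    expect_within(fit_eta, direct_eta, 0.05)
  }
  # no DFE parameters in a control-only fit
  expect_false(any(grepl("^mu\\[|^sigma\\[", sm$parameter)))
})

test_that("posterior uncertainty for genetic values shrinks with sample size", {
  founders <- data.frame(
    founder_id = c("big", "small"), y = c(2.9, 2.9),
    n_ems_lines = 0L, n_control_plants = c(600L, 40L), eta = 0.25,
    stringsAsFactors = FALSE
  )
  cfg <- simulation_config(founders = founders, dfe = list(),
                           n_blocks = 4, seed = 26)
  tab <- simulate_experiment(cfg)
  fit <- suppressWarnings(fit_variational(build_model(tab, small_fit_config(seed = 4))))
  sm <- fit$summary
  sd_big <- sm$sd[sm$parameter == "y[big]"]
  sd_small <- sm$sd[sm$parameter == "y[small]"]
  expect_gt(sd_small, sd_big)
})

test_that("credible-interval exclusion checks behave like interval logic", {
  tab <- simulate_experiment(small_sim_config(seed = 27))
  fit <- suppressWarnings(fit_variational(build_model(tab, small_fit_config(seed = 6))))
  sm <- fit$summary
  row <- sm[sm$parameter == "y[A]", ]
  mid <- (row$q2.5 + row$q97.5) / 2
  expect_false(posterior_credible_check(fit, "y[A]", 0.95, mid))
  expect_true(posterior_credible_check(fit, "y[A]", 0.95, row$q97.5 + 1))
  expect_true(posterior_credible_check(fit, "y[A]", 0.99, -50))
  expect_error(posterior_credible_check(fit, "nope", 0.95, 0), "unknown parameter")
  expect_error(posterior_credible_check(fit, "y[A]", 0.5, 0), "level")
})
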