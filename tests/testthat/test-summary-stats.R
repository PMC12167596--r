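test_that("group summaries match hand arithmetic and flag degenerate groups", {
  gs <- group_summaries(tiny_table())
  expect_equal(gs$n_seedlings, 4)
  expect_equal(gs$survival_rate, 0.5)
  expect_equal(gs$mean_log10_weight, 2.5)
  expect_equal(gs$sd_log10_weight, sqrt(0.5), tolerance = 1e-12)

  dead <- experiment_table(data.frame(
    founder_id = "A", line_id = "control", subline_id = "1", block_id = "1",
    ems_treated = FALSE, survived = FALSE, dry_weight_mg = 0,
    stringsAsFactors = FALSE
  ))
  gd <- group_summaries(dead)
  expect_equal(gd$survival_rate, 0)
  expect_true(is.na(gd$mean_log10_weight))
  expect_true(is.na(gd$sd_log10_weight))

  # per-line grouping splits the EMS lines
  tab <- simulate_experiment(small_sim_config(seed = 31))
  gl <- group_summaries(tab, grouping = "line")
  expect_equal(nrow(gl), 4 + 2)   # 4 mutant lines + 2 control lines
})

test_that("the exact albino test equals brute-force hypergeometric enumeration", {
  # independent brute force built directly from dhyper over the support
  brute <- function(a, n_a, b, n_b) {
    K <- a + b; N <- n_a + n_b
    supp <- max(0, K - n_b):min(n_a, K)
    pr <- stats::dhyper(supp, K, N - K, n_a)
    sum(pr[pr <= pr[supp == a] * (1 + 1e-7)])
  }
  grid <- expand.grid(a = 0:5, b = 0:5, n_a = c(5, 9, 14), n_b = c(5, 20))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    if (g$a > g$n_a || g$b > g$n_b) next
    ours <- albino_fisher_test(g$a, g$n_a, g$b, g$n_b)$p_value
    expect_equal(ours, min(brute(g$a, g$n_a, g$b, g$n_b), 1), tolerance = 1e-12)
    expect_equal(ours,
                 stats::fisher.test(matrix(c(g$a, g$n_a - g$a,
                                             g$b, g$n_b - g$b), 2))$p.value,
                 tolerance = 1e-9)
  }
  expect_equal(albino_fisher_test(0, 10, 0, 10)$p_value, 1)
  expect_lt(albino_fisher_test(10, 10, 0, 10)$p_value, 0.001)
  expect_error(albino_fisher_test(5, 3, 1, 10), "counts")
})

test_that("line-vs-control counting includes mortality zeros by convention", {
  mk <- function(line, weights, survived, ems = TRUE) data.frame(
    founder_id = "A", line_id = line, subline_id = "1", block_id = "1",
    ems_treated = ems, survived = survived, dry_weight_mg = weights,
    stringsAsFactors = FALSE
  )
  tab <- experiment_table(rbind(
    mk("control", c(100, 100, 100, 100), TRUE, ems = FALSE),
    mk("L1", c(1000, 1000, 1000, 1000), TRUE),          # above control
    mk("L2", c(1000, 1000, 0, 0), c(TRUE, TRUE, FALSE, FALSE)),  # zeros drag below
    mk("L3", c(10, 10, 10, 10), TRUE)                   # below control
  ))
  res <- count_lines_above_control(tab, "A")
  expect_equal(res$n_lines, 3)
  expect_equal(res$n_above, 1)
  # survivors-only view rescues the line with dead plants
  res2 <- count_lines_above_control(tab, "A", include_zeros = FALSE)
  expect_equal(res2$n_above, 2)
  expect_error(count_lines_above_control(tab[tab$ems_treated, ], "A"),
               "no control")
})

test_that("many-to-one comparisons flag a strongly shifted line and nothing else", {
  set.seed(33)
  cfg <- small_sim_config(seed = 33, survival_c = 0, survival_d = -20)
  tab <- simulate_experiment(cfg)          # everyone survives
  expect_true(all(tab$survived))
  # shift line L2 upward by ~5 control SDs
  up <- tab$line_id == "L2"
  tab$dry_weight_mg[up] <- tab$dry_weight_mg[up] * 10
  res <- compare_lines_to_control(tab, "A", alternative = "greater")
  expect_false(is.null(res$all_plants))
  flagged <- res$all_plants$line_id[res$all_plants$p_adjusted < 0.05]
  expect_true("L2" %in% flagged)
  surv_flagged <- res$survivors$line_id[res$survivors$p_adjusted < 0.05]
  expect_true("L2" %in% surv_flagged)
  expect_error(compare_lines_to_control(tab, "B"), "no mutant lines")
})

test_that("null many-to-one comparisons keep the family-wise error near nominal", {
  set.seed(34)
  n_rep <- 250
  fp <- 0
  groups <- factor(rep(c("control", paste0("L", 1:5)), each = 12),
                   levels = c("control", paste0("L", 1:5)))
  base <- data.frame(
    founder_id = "A", line_id = as.character(groups),
    subline_id = "1", block_id = "1",
    ems_treated = groups != "control", survived = TRUE,
    stringsAsFactors = FALSE
  )
  for (r in seq_len(n_rep)) {
    base$dry_weight_mg <- 10^rnorm(nrow(base), 2.5, 0.3)
    tab <- experiment_table(base)
    res <- compare_lines_to_control(tab, "A", alternative = "greater")
    if (any(res$all_plants$p_adjusted < 0.05)) fp <- fp + 1
  }
  # familywise rate should be ~0.05; allow Monte Carlo slack (4 binomial SEs)
  expect_lt(fp / n_rep, 0.05 + 4 * sqrt(0.05 * 0.95 / n_rep))
})
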