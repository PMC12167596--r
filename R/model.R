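# Hierarchical Bayesian zero-inflated fitness model, fitted by stochastic
# variational inference.
#
# Observation model for plant p (founder f, subline k, block l):
#   s_p = y_f + m_k + h_p + b_l
#   survival ~ Bernoulli(1 / (1 + exp(c * s_p + d)))
#   z_p | survived ~ Normal(s_p, eta_f^2),  z_p = log10 dry weight
# For plants of EMS lines the mutational deviation h_p is decomposed, via
# the central-limit approximation to the compound-Poisson sum of mutation
# effects, into three normal terms tied to the DFE moments (mu_f, sigma_f):
#   h_p = lambda * mu_f + sqrt(v1) L_line + sqrt(v2) S_subline + sqrt(v3) I_p
# with (v1, v2, v3) = (c1, c2, c3) * lambda * (mu_f^2 + sigma_f^2) obtained
# from the exact dosage cross-moments (1.5, 0.25, 0.125 of the total 1.875
# coefficient in the default three-generation design).  Control plants have
# h = 0.  The line-level term carries the full mean lambda * mu_f; subline
# and individual terms are zero-mean.
#
# Inference: stochastic variational approximation (ADVI-style).  All
# parameters and latent effects live in an unconstrained vector (positive
# scales via log), latent effects use the non-centered parameterization,
# and the evidence lower bound is maximized by Adam on single-sample
# reparameterized gradients, coded analytically below.  The default
# approximating family is structured: a full-covariance Gaussian over the
# global parameters (learned in whitened coordinates after a mean-field
# warm start) and independent normals over the local latent effects; a
# fully factorized family is available as an option.

#' Configuration of the hierarchical model and its variational fit
#'
#' Priors (all weakly informative, on the log10-mg scale): founder genetic
#' values `y ~ Normal(0, prior_y_sd^2)`; DFE mean `mu ~ Normal(0,
#' prior_mu_sd^2)`; DFE SD `sigma ~ HalfNormal(prior_sigma_sd)`; maternal
#' and block SDs `~ HalfNormal(prior_scale_sd)`; residual SDs `eta ~
#' HalfNormal(prior_eta_sd)`; survival parameters `c, d ~ Normal(0,
#' prior_cd_sd^2)`.  `lambda_mut` and the selfing design are fixed inputs of
#' the analysis, never estimated.
#'
#' @param lambda_mut fixed mean number of induced mutations per line.
#' @param g,g_line,g_subline selfing design passed to
#'   [compound_poisson_moments()].
#' @param prior_y_sd,prior_mu_sd,prior_sigma_sd,prior_scale_sd,prior_eta_sd,prior_cd_sd
#'   prior scales, see Details.
#' @param max_iter optimizer iterations of the factorized stage.
#' @param cov_iter additional iterations of the global-covariance stage
#'   (structured approximation only).
#' @param learning_rate Adam step size.
#' @param tol convergence tolerance on the relative change of the smoothed
#'   objective between successive windows.
#' @param window iterations per convergence-check window.
#' @param n_restarts independent restarts; the fit with the highest final
#'   smoothed objective wins, ties broken by lowest restart index.
#' @param n_draws posterior draws used for summaries.
#' @param approx `"structured"` (default): full-rank Gaussian over the
#'   global parameters (genetic values, DFE moments, scales, survival
#'   parameters) and independent normals over the local latent effects,
#'   so that the strong posterior correlation between founder genetic
#'   values and DFE means is reflected in the reported marginals;
#'   `"meanfield"`: fully factorized.
#' @param seed RNG seed for the stochastic optimizer and summary draws.
#' @return Object of class `model_config` (a list).
#' @export
model_config <- function(lambda_mut = 25, g = 3, g_line = 1, g_subline = 2,
                         prior_y_sd = 10, prior_mu_sd = 0.05,
                         prior_sigma_sd = 0.05, prior_scale_sd = 0.1,
                         prior_eta_sd = 1, prior_cd_sd = 5,
                         max_iter = 20000, cov_iter = 10000,
                         learning_rate = 0.02,
                         tol = 2e-4, window = 500,
                         n_restarts = 1, n_draws = 4000,
                         approx = c("structured", "meanfield"),
                         seed = 1L) {
  approx <- match.arg(approx)
  stopifnot(lambda_mut > 0, g >= 2, max_iter >= 100, cov_iter >= 100,
            learning_rate > 0,
            tol > 0, window >= 10, n_restarts >= 1, n_draws >= 100)
  structure(as.list(environment()), class = "model_config")
}

#' Build the hierarchical zero-inflated fitness model
#'
#' Assembles the index structures and data vectors tying every plant to its
#' founder, subline, block and (for EMS plants) line/subline/individual
#' mutational terms.  Founders carrying any EMS-treated line are the focal
#' founders and receive DFE parameters (mu, sigma); a table with no EMS
#' plants yields a model without DFE parameters.
#'
#' @param table an [experiment_table()].
#' @param config a [model_config()].
#' @return Object of class `dfe_model`.
#' @export
build_model <- function(table, config = model_config()) {
  stopifnot(inherits(table, "experiment_table"), inherits(config, "model_config"))
  f_levels <- sort(unique(table$founder_id))
  f_idx <- match(table$founder_id, f_levels)
  focal <- sort(unique(table$founder_id[table$ems_treated]))
  no_control <- focal[!vapply(focal, function(ff)
    any(table$founder_id == ff & !table$ems_treated), logical(1))]
  if (length(no_control))
    warning("focal founder(s) without control plants: ",
            paste(no_control, collapse = ", "),
            "; genetic value identified from EMS lines only", call. = FALSE)
  sub_key <- paste(table$founder_id, table$line_id, table$subline_id)
  sub_levels <- unique(sub_key)
  k_idx <- match(sub_key, sub_levels)
  b_levels <- sort(unique(table$block_id))
  l_idx <- match(table$block_id, b_levels)

  ems <- which(table$ems_treated)
  fe_levels <- focal
  fe_of_plant <- match(table$founder_id[ems], fe_levels)
  line_key <- paste(table$founder_id[ems], table$line_id[ems])
  line_levels <- unique(line_key)
  j_idx <- match(line_key, line_levels)
  esub_levels <- unique(sub_key[ems])
  ks_idx <- match(sub_key[ems], esub_levels)
  fe_of_line <- fe_of_plant[match(line_levels, line_key)]
  fe_of_esub <- fe_of_plant[match(esub_levels, sub_key[ems])]

  dm <- dosage_moments(config$g)
  cmv <- dm$cross_moment(c(config$g_line, config$g_subline))
  dos_coef <- c(line = cmv[1], subline = cmv[2] - cmv[1],
                individual = dm$second_moment - cmv[2])

  surv <- table$survived
  z <- ifelse(surv, log10(table$dry_weight_mg), 0)

  structure(list(
    table = table, config = config,
    founders = f_levels, focal = fe_levels,
    sublines = sub_levels, blocks = b_levels,
    lines = line_levels,
    n_plants = nrow(table), n_ems = length(ems),
    f_idx = f_idx, k_idx = k_idx, l_idx = l_idx,
    ems = ems, fe_of_plant = fe_of_plant,
    j_idx = j_idx, ks_idx = ks_idx,
    fe_of_line = fe_of_line, fe_of_esub = fe_of_esub,
    dos_coef = dos_coef,
    surv = surv, z = z
  ), class = "dfe_model")
}

#' @export
print.dfe_model <- function(x, ...) {
  cat("Hierarchical zero-inflated fitness model\n")
  cat("  plants:", x$n_plants, "(", x$n_ems, "in EMS lines )\n")
  cat("  founders:", length(x$founders),
      "| focal (DFE):", if (length(x$focal)) paste(x$focal, collapse = ", ")
      else "none", "\n")
  cat("  sublines:", length(x$sublines), "| blocks:", length(x$blocks),
      "| EMS lines:", length(x$lines), "\n")
  invisible(x)
}

# ---- parameter vector layout -------------------------------------------

.param_layout <- function(model) {
  F <- length(model$founders); Fe <- length(model$focal)
  K <- length(model$sublines); B <- length(model$blocks)
  J <- length(model$lines); Ks <- length(unique(model$ks_idx))
  Ne <- model$n_ems
  sizes <- c(y = F, mu = Fe, ls = Fe, lsm = 1, lsb = 1, le = F,
             cpar = 1, dpar = 1, braw = B, mraw = K,
             Lraw = J, Sraw = Ks, Iraw = Ne)
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1
  lay <- Map(function(a, b) if (b < a) integer(0) else seq(a, b), starts, ends)
  names(lay) <- names(sizes)
  lay$D <- sum(sizes)
  lay$n_global <- ends[["dpar"]]
  lay
}

# log joint density and its gradient at unconstrained theta; everything
# vectorized over plants, group sums via rowsum()
.logp_grad <- function(theta, model) {
  cfg <- model$config
  lay <- model$layout
  lam <- cfg$lambda_mut
  Fe <- length(model$focal)
  grad <- numeric(lay$D)

  y <- theta[lay$y]
  le <- theta[lay$le]; eta <- exp(le)
  lsm <- theta[lay$lsm]; sdm <- exp(lsm)
  lsb <- theta[lay$lsb]; sdb <- exp(lsb)
  cpar <- theta[lay$cpar]; dpar <- theta[lay$dpar]
  braw <- theta[lay$braw]; mraw <- theta[lay$mraw]

  s <- y[model$f_idx] + sdm * mraw[model$k_idx] + sdb * braw[model$l_idx]

  if (Fe > 0) {
    mu <- theta[lay$mu]
    ls <- theta[lay$ls]; sig <- exp(ls)
    Lraw <- theta[lay$Lraw]; Sraw <- theta[lay$Sraw]; Iraw <- theta[lay$Iraw]
    a <- lam * (mu^2 + sig^2)                  # per focal founder
    sq1 <- sqrt(model$dos_coef[["line"]] * a)
    sq2 <- sqrt(model$dos_coef[["subline"]] * a)
    sq3 <- sqrt(model$dos_coef[["individual"]] * a)
    hL <- sq1[model$fe_of_line] * Lraw
    hS <- sq2[model$fe_of_esub] * Sraw
    hI <- sq3[model$fe_of_plant] * Iraw
    h <- lam * mu[model$fe_of_plant] + hL[model$j_idx] + hS[model$ks_idx] + hI
    s[model$ems] <- s[model$ems] + h
  }

  t_lin <- cpar * s + dpar
  # survival: log p = -log1p(exp(t)) if survived, t - log1p(exp(t)) if dead
  sig_t <- stats::plogis(t_lin)
  lp_surv <- ifelse(model$surv, stats::plogis(-t_lin, log.p = TRUE),
                    stats::plogis(t_lin, log.p = TRUE))
  g_t <- (!model$surv) - sig_t

  eta_p <- eta[model$f_idx]
  resid <- model$z - s
  lp_w <- ifelse(model$surv,
                 -log(eta_p) - resid^2 / (2 * eta_p^2), 0)
  g_s <- cpar * g_t + ifelse(model$surv, resid / eta_p^2, 0)

  logp <- sum(lp_surv) + sum(lp_w)

  # observation-level gradients back to parameters
  grad[lay$cpar] <- sum(g_t * s)
  grad[lay$dpar] <- sum(g_t)
  gy <- rowsum(g_s, model$f_idx)
  grad[lay$y] <- gy[, 1]
  gk <- rowsum(g_s, model$k_idx)
  grad[lay$mraw] <- sdm * gk[, 1]
  grad[lay$lsm] <- sum(gk[, 1] * sdm * mraw)
  gl <- rowsum(g_s, model$l_idx)
  grad[lay$braw] <- sdb * gl[, 1]
  grad[lay$lsb] <- sum(gl[, 1] * sdb * braw)
  gw <- ifelse(model$surv, -1 + resid^2 / eta_p^2, 0)
  gle <- rowsum(gw, model$f_idx)
  grad[lay$le] <- gle[, 1]

  if (Fe > 0) {
    g_se <- g_s[model$ems]
    gJ <- rowsum(g_se, model$j_idx)
    grad[lay$Lraw] <- sq1[model$fe_of_line] * gJ[, 1]
    gKs <- rowsum(g_se, model$ks_idx)
    grad[lay$Sraw] <- sq2[model$fe_of_esub] * gKs[, 1]
    grad[lay$Iraw] <- sq3[model$fe_of_plant] * g_se
    # mu and log-sigma through the mean and the three scale factors;
    # d sqrt(cj * a) / d mu = cj * lam * mu / sqrt(cj * a), similarly for
    # sigma with d a / d ls = 2 lam sigma^2
    wL <- rowsum(g_se * hL[model$j_idx] / a[model$fe_of_plant], model$fe_of_plant,
                 reorder = TRUE)
    wS <- rowsum(g_se * hS[model$ks_idx] / a[model$fe_of_plant], model$fe_of_plant,
                 reorder = TRUE)
    wI <- rowsum(g_se * hI / a[model$fe_of_plant], model$fe_of_plant,
                 reorder = TRUE)
    wsum <- numeric(Fe)
    wsum[as.integer(rownames(wL))] <- (wL + wS + wI)[, 1] / 2
    gmean <- rowsum(g_se, model$fe_of_plant)
    gmu_mean <- numeric(Fe)
    gmu_mean[as.integer(rownames(gmean))] <- lam * gmean[, 1]
    grad[lay$mu] <- gmu_mean + wsum * 2 * lam * mu
    grad[lay$ls] <- wsum * 2 * lam * sig^2
  }

  # priors (and change-of-variable jacobians for log-scales)
  logp <- logp +
    sum(stats::dnorm(y, 0, cfg$prior_y_sd, log = TRUE)) +
    sum(stats::dnorm(c(cpar, dpar), 0, cfg$prior_cd_sd, log = TRUE)) +
    sum(-eta^2 / (2 * cfg$prior_eta_sd^2) + le) +
    (-sdm^2 / (2 * cfg$prior_scale_sd^2) + lsm) +
    (-sdb^2 / (2 * cfg$prior_scale_sd^2) + lsb) +
    sum(stats::dnorm(braw, log = TRUE)) + sum(stats::dnorm(mraw, log = TRUE))
  grad[lay$y] <- grad[lay$y] - y / cfg$prior_y_sd^2
  grad[lay$cpar] <- grad[lay$cpar] - cpar / cfg$prior_cd_sd^2
  grad[lay$dpar] <- grad[lay$dpar] - dpar / cfg$prior_cd_sd^2
  grad[lay$le] <- grad[lay$le] - eta^2 / cfg$prior_eta_sd^2 + 1
  grad[lay$lsm] <- grad[lay$lsm] - sdm^2 / cfg$prior_scale_sd^2 + 1
  grad[lay$lsb] <- grad[lay$lsb] - sdb^2 / cfg$prior_scale_sd^2 + 1
  grad[lay$braw] <- grad[lay$braw] - braw
  grad[lay$mraw] <- grad[lay$mraw] - mraw
  if (Fe > 0) {
    logp <- logp +
      sum(stats::dnorm(mu, 0, cfg$prior_mu_sd, log = TRUE)) +
      sum(-sig^2 / (2 * cfg$prior_sigma_sd^2) + ls) +
      sum(stats::dnorm(Lraw, log = TRUE)) +
      sum(stats::dnorm(Sraw, log = TRUE)) +
      sum(stats::dnorm(Iraw, log = TRUE))
    grad[lay$mu] <- grad[lay$mu] - mu / cfg$prior_mu_sd^2
    grad[lay$ls] <- grad[lay$ls] - sig^2 / cfg$prior_sigma_sd^2 + 1
    grad[lay$Lraw] <- grad[lay$Lraw] - Lraw
    grad[lay$Sraw] <- grad[lay$Sraw] - Sraw
    grad[lay$Iraw] <- grad[lay$Iraw] - Iraw
  }
  list(logp = logp, grad = grad)
}

# data-driven initialization of the variational means
.init_means <- function(model) {
  lay <- model$layout
  m <- numeric(lay$D)
  tab <- model$table
  zs <- model$z
  overall <- mean(zs[model$surv])
  if (!is.finite(overall)) overall <- 0
  ymean <- tapply(zs[model$surv], model$f_idx[model$surv], mean)
  y0 <- rep(overall, length(model$founders))
  y0[as.integer(names(ymean))] <- ymean
  m[lay$y] <- y0
  ysd <- tapply(zs[model$surv], model$f_idx[model$surv], stats::sd)
  e0 <- rep(0.3, length(model$founders))
  ok <- !is.na(ysd) & ysd > 0
  e0[as.integer(names(ysd))[ok]] <- ysd[ok]
  m[lay$le] <- log(e0)
  m[lay$lsm] <- log(0.02); m[lay$lsb] <- log(0.02)
  if (length(lay$ls)) m[lay$ls] <- log(0.01)
  # logistic survival initialized by a marginal regression of death on the
  # founder-mean genetic value
  s0 <- y0[model$f_idx]
  cd <- tryCatch(
    stats::coef(stats::glm((!model$surv) ~ s0, family = stats::binomial())),
    warning = function(w) c(0, 0), error = function(e) c(0, 0))
  if (any(!is.finite(cd))) cd <- c(0, 0)
  m[lay$cpar] <- cd[2]; m[lay$dpar] <- cd[1]
  m
}

#' Fit the model by mean-field variational inference
#'
#' Maximizes the evidence lower bound of a fully factorized Gaussian
#' approximation on the unconstrained parameter space (positive scales log
#' transformed, latent effects non-centered) with Adam on single-sample
#' reparameterized gradients.  Convergence is declared when the relative
#' change of the exponentially smoothed objective between successive
#' windows falls below `tol`; non-convergence within `max_iter` flags the
#' result but still returns it.  With `n_restarts > 1` the restart with the
#' highest final smoothed objective is returned (ties: lowest index).
#'
#' @param model a [build_model()] result.
#' @param config optional [model_config()] overriding `model$config`.
#' @return Object of class `dfe_posterior`: list with `summary` (data frame:
#'   `parameter`, `mean`, `sd`, `q2.5`, `q97.5`, `q0.5`, `q99.5`),
#'   `converged`, `iterations`, `elbo` (final smoothed objective), `trace`
#'   (smoothed objective per window), `draws` (matrix of posterior draws of
#'   the interpretable parameters), and `model`.
#' @export
fit_variational <- function(model, config = NULL) {
  stopifnot(inherits(model, "dfe_model"))
  if (!is.null(config)) model$config <- config
  cfg <- model$config
  model$layout <- .param_layout(model)
  lay <- model$layout
  set.seed(cfg$seed)

  best <- NULL
  for (r in seq_len(cfg$n_restarts)) {
    fit <- .advi_run(model, jitter = (r - 1) * 0.1)
    if (is.null(best) || fit$elbo > best$elbo) { fit$restart <- r; best <- fit }
  }
  .posterior_summarize(best, model)
}

.advi_run <- function(model, jitter = 0) {
  cfg <- model$config
  lay <- model$layout
  D <- lay$D
  ng <- if (cfg$approx == "structured") lay$n_global else 0L
  loc <- (ng + 1):D

  # stage 1: fully factorized fit of all D coordinates
  s1 <- .advi_meanfield(model, jitter)
  if (ng == 0L)
    return(list(m = s1$m, lsq = s1$lsq, ng = 0L, L = NULL, elbo = s1$elbo,
                trace = s1$trace, converged = s1$converged,
                iterations = s1$iterations))

  # stage 2: learn a full covariance for the global block in whitened
  # coordinates, theta_G = m_G + diag(base) L ζ with base the stage-1
  # marginal SDs, so every Cholesky entry is O(1); local coordinates keep
  # their independent normals and continue to adapt
  s2 <- .advi_fullrank_global(model, s1, ng)
  L_out <- diag(s2$base, ng) %*% s2$Lt
  list(m = s2$m, lsq = s2$lsq, ng = ng, L = L_out,
       elbo = s2$elbo, trace = c(s1$trace, s2$trace),
       converged = s1$converged && s2$converged,
       iterations = s1$iterations + s2$iterations)
}

# shared Adam schedule: constant step for the first 60% of a run, linear
# decay to 10% afterwards; reported parameters are Polyak averages over the
# final 25% of iterations so point estimates are not hostage to
# single-sample gradient noise
.advi_schedule <- function(it, n_iter, lr0) {
  frac <- it / n_iter
  lr0 * if (frac <= 0.6) 1 else max(0.1, 1 - 2.25 * (frac - 0.6))
}

.advi_meanfield <- function(model, jitter = 0) {
  cfg <- model$config
  D <- model$layout$D
  m <- .init_means(model)
  if (jitter > 0) m <- m + stats::rnorm(D, 0, jitter * 0.1)
  lsq <- rep(-2.5, D)
  b1 <- 0.9; b2 <- 0.999; epsl <- 1e-8
  mo <- numeric(2 * D); vo <- numeric(2 * D)
  ema <- NA_real_; ema_decay <- 0.99
  trace <- numeric(0); converged <- FALSE; last_win <- NA_real_
  avg_from <- ceiling(0.75 * cfg$max_iter)
  avg <- numeric(2 * D); n_avg <- 0
  for (it in seq_len(cfg$max_iter)) {
    zeta <- stats::rnorm(D)
    sdq <- exp(lsq)
    theta <- m + sdq * zeta
    lg <- .logp_grad(theta, model)
    g <- c(lg$grad, lg$grad * sdq * zeta + 1)   # d/dm, d/dlsq (+entropy)
    mo <- b1 * mo + (1 - b1) * g
    vo <- b2 * vo + (1 - b2) * g^2
    step <- .advi_schedule(it, cfg$max_iter, cfg$learning_rate) *
      (mo / (1 - b1^it)) / (sqrt(vo / (1 - b2^it)) + epsl)
    m <- m + step[seq_len(D)]
    lsq <- pmin(lsq + step[D + seq_len(D)], 5)
    if (it >= avg_from) {
      n_avg <- n_avg + 1
      avg <- avg + (c(m, lsq) - avg) / n_avg
    }
    elbo_hat <- lg$logp + sum(lsq)
    ema <- if (is.na(ema)) elbo_hat else ema_decay * ema + (1 - ema_decay) * elbo_hat
    if (it %% cfg$window == 0) {
      trace <- c(trace, ema)
      if (!is.na(last_win) && it >= avg_from) {
        rel <- abs(ema - last_win) / (abs(last_win) + 1e-10)
        converged <- converged || rel < cfg$tol
      }
      last_win <- ema
    }
  }
  if (n_avg == 0) avg <- c(m, lsq)
  if (!converged)
    warning("variational fit did not reach the convergence tolerance within ",
            cfg$max_iter, " iterations; returning the flagged result",
            call. = FALSE)
  list(m = avg[seq_len(D)], lsq = avg[D + seq_len(D)], elbo = ema,
       trace = trace, converged = converged, iterations = cfg$max_iter)
}

.advi_fullrank_global <- function(model, s1, ng) {
  cfg <- model$config
  D <- model$layout$D
  loc <- (ng + 1):D
  n_iter <- cfg$cov_iter
  base <- exp(s1$lsq[seq_len(ng)])
  m <- s1$m
  ld <- numeric(ng)                       # log diag of whitened Cholesky
  off_idx <- which(lower.tri(diag(ng)))
  noff <- length(off_idx)
  loff <- numeric(noff)
  lsq <- s1$lsq[loc]
  nl <- length(loc)
  P <- D + ng + noff + nl
  b1 <- 0.9; b2 <- 0.999; epsl <- 1e-8
  mo <- numeric(P); vo <- numeric(P)
  ema <- NA_real_; ema_decay <- 0.99
  trace <- numeric(0); converged <- FALSE; last_win <- NA_real_
  avg_from <- ceiling(0.75 * n_iter)
  avg <- numeric(P); n_avg <- 0
  Lt <- matrix(0, ng, ng)
  for (it in seq_len(n_iter)) {
    zeta <- stats::rnorm(D)
    Lt[off_idx] <- loff
    diag(Lt) <- exp(ld)
    theta <- numeric(D)
    zG <- zeta[seq_len(ng)]
    theta[seq_len(ng)] <- m[seq_len(ng)] + base * drop(Lt %*% zG)
    sdl <- exp(lsq)
    theta[loc] <- m[loc] + sdl * zeta[loc]
    lg <- .logp_grad(theta, model)
    gG <- lg$grad[seq_len(ng)] * base       # gradient in whitened scale
    gld <- gG * zG * diag(Lt) + 1           # + entropy
    gloff <- tcrossprod(gG, zG)[off_idx]
    glsq <- lg$grad[loc] * sdl * zeta[loc] + 1
    g <- c(lg$grad, gld, gloff, glsq)
    mo <- b1 * mo + (1 - b1) * g
    vo <- b2 * vo + (1 - b2) * g^2
    step <- .advi_schedule(it, n_iter, 0.5 * cfg$learning_rate) *
      (mo / (1 - b1^it)) / (sqrt(vo / (1 - b2^it)) + epsl)
    m <- m + step[seq_len(D)]
    ld <- pmin(ld + step[D + seq_len(ng)], 4)
    loff <- loff + step[D + ng + seq_len(noff)]
    lsq <- pmin(lsq + step[D + ng + noff + seq_len(nl)], 5)
    if (it >= avg_from) {
      n_avg <- n_avg + 1
      avg <- avg + (c(m, ld, loff, lsq) - avg) / n_avg
    }
    elbo_hat <- lg$logp + sum(ld) + sum(log(base)) + sum(lsq)
    ema <- if (is.na(ema)) elbo_hat else ema_decay * ema + (1 - ema_decay) * elbo_hat
    if (it %% cfg$window == 0) {
      trace <- c(trace, ema)
      if (!is.na(last_win) && it >= avg_from) {
        rel <- abs(ema - last_win) / (abs(last_win) + 1e-10)
        converged <- converged || rel < cfg$tol
      }
      last_win <- ema
    }
  }
  if (n_avg == 0) avg <- c(m, ld, loff, lsq)
  m <- avg[seq_len(D)]
  ld <- avg[D + seq_len(ng)]
  loff <- avg[D + ng + seq_len(noff)]
  lsq <- avg[D + ng + noff + seq_len(nl)]
  Lt <- matrix(0, ng, ng)
  Lt[off_idx] <- loff
  diag(Lt) <- exp(ld)
  list(m = m, lsq = lsq, base = base, Lt = Lt, elbo = ema, trace = trace,
       converged = converged, iterations = n_iter)
}

.posterior_summarize <- function(fit, model) {
  cfg <- model$config
  lay <- model$layout
  Fe <- length(model$focal)
  idx <- c(lay$y, lay$mu, lay$ls, lay$le, lay$lsm, lay$lsb, lay$cpar, lay$dpar)
  nm <- c(paste0("y[", model$founders, "]"),
          if (Fe) paste0("mu[", model$focal, "]"),
          if (Fe) paste0("sigma[", model$focal, "]"),
          paste0("eta[", model$founders, "]"),
          "maternal_sd", "block_sd", "c", "d")
  is_log <- c(rep(FALSE, length(model$founders)),
              rep(FALSE, Fe), rep(TRUE, Fe),
              rep(TRUE, length(model$founders)),
              TRUE, TRUE, FALSE, FALSE)
  nd <- cfg$n_draws
  if (fit$ng > 0) {
    Zg <- matrix(stats::rnorm(nd * fit$ng), nrow = nd)
    thetaG <- sweep(Zg %*% t(fit$L), 2, fit$m[seq_len(fit$ng)], "+")
    draws <- thetaG[, idx, drop = FALSE]
  } else {
    draws <- matrix(stats::rnorm(nd * length(idx)), nrow = nd)
    draws <- sweep(draws, 2, exp(fit$lsq[idx]), "*")
    draws <- sweep(draws, 2, fit$m[idx], "+")
  }
  draws[, is_log] <- exp(draws[, is_log])
  colnames(draws) <- nm
  qs <- apply(draws, 2, stats::quantile, probs = c(0.025, 0.975, 0.005, 0.995))
  summary <- data.frame(
    parameter = nm,
    mean = colMeans(draws),
    sd = apply(draws, 2, stats::sd),
    q2.5 = qs[1, ], q97.5 = qs[2, ], q0.5 = qs[3, ], q99.5 = qs[4, ],
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(summary = summary, draws = draws,
                 converged = fit$converged, iterations = fit$iterations,
                 elbo = fit$elbo, trace = fit$trace,
                 restart = fit$restart,
                 m = fit$m, lsq = fit$lsq, L = fit$L, ng = fit$ng,
                 model = model),
            class = "dfe_posterior")
}

#' @export
print.dfe_posterior <- function(x, digits = 4, ...) {
  cat("Variational posterior (",
      if (x$converged) "converged" else "NOT converged",
      " after ", x$iterations, " iterations, ELBO ~ ",
      format(x$elbo, digits = 8), ")\n", sep = "")
  out <- x$summary
  out[, -1] <- signif(out[, -1], digits)
  print(out, row.names = FALSE)
  invisible(x)
}

#' Is a value excluded by a posterior credible interval?
#'
#' @param posterior a `dfe_posterior` from [fit_variational()].
#' @param parameter parameter name as in `posterior$summary$parameter`.
#' @param level credible level, 0.95 or 0.99.
#' @param value the value to test (e.g. 0).
#' @return `TRUE` iff `value` lies outside the central credible interval at
#'   `level`.
#' @export
posterior_credible_check <- function(posterior, parameter, level = 0.95,
                                     value = 0) {
  stopifnot(inherits(posterior, "dfe_posterior"))
  row <- posterior$summary[posterior$summary$parameter == parameter, ]
  if (nrow(row) != 1)
    stop("unknown parameter: ", parameter, call. = FALSE)
  if (isTRUE(all.equal(level, 0.95))) {
    lo <- row$q2.5; hi <- row$q97.5
  } else if (isTRUE(all.equal(level, 0.99))) {
    lo <- row$q0.5; hi <- row$q99.5
  } else stop("level must be 0.95 or 0.99", call. = FALSE)
  value < lo || value > hi
}
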