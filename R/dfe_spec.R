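#' Specify a distribution of single-mutation fitness effects
#'
#' A `dfe_spec` describes the distribution from which the fitness effect of a
#' single induced mutation is drawn, on the log10-milligram biomass scale.
#' Every family carries its first two moments (`mu`, `sigma`) in closed form:
#' the inference machinery only ever uses these two moments, while the
#' simulator samples from the full distribution so that robustness of the
#' normal approximation to the shape of the DFE can be exercised.
#'
#' Supported families:
#' \describe{
#'   \item{`point_mass`}{all mutations share effect `value`.}
#'   \item{`normal`}{`mean`, `sd`.}
#'   \item{`gamma_deleterious`}{effect = minus a Gamma(`shape`, scale =
#'     `scale`) draw; strictly deleterious, right-skewed magnitude.}
#'   \item{`reflected_gamma`}{effect = plus a Gamma(`shape`, scale =
#'     `scale`) draw; strictly beneficial mirror image.}
#'   \item{`two_component_mixture`}{mixture of two normals with weight `w`
#'     on component 1 (`mean1`, `sd1`) and `1 - w` on component 2
#'     (`mean2`, `sd2`); allows bimodal DFEs.}
#' }
#'
#' @param family character; one of the families above.
#' @param ... family parameters, see Details.
#' @return An object of class `dfe_spec` with elements `family`, `params`,
#'   `mu` (mean effect) and `sigma` (SD of effects).
#' @examples
#' dfe_spec("normal", mean = 0.004, sd = 0.015)
#' dfe_spec("gamma_deleterious", shape = 2, scale = 0.005)
#' @export
dfe_spec <- function(family = c("point_mass", "normal", "gamma_deleterious",
                                "reflected_gamma", "two_component_mixture"),
                     ...) {
  family <- match.arg(family)
  params <- list(...)
  need <- function(nms) {
    miss <- setdiff(nms, names(params))
    if (length(miss))
      stop("dfe_spec('", family, "') requires parameter(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
  }
  mom <- switch(family,
    point_mass = {
      need("value")
      c(params$value, 0)
    },
    normal = {
      need(c("mean", "sd"))
      if (params$sd < 0) stop("sd must be non-negative", call. = FALSE)
      c(params$mean, params$sd)
    },
    gamma_deleterious = {
      need(c("shape", "scale"))
      if (params$shape <= 0 || params$scale <= 0)
        stop("shape and scale must be positive", call. = FALSE)
      c(-params$shape * params$scale, sqrt(params$shape) * params$scale)
    },
    reflected_gamma = {
      need(c("shape", "scale"))
      if (params$shape <= 0 || params$scale <= 0)
        stop("shape and scale must be positive", call. = FALSE)
      c(params$shape * params$scale, sqrt(params$shape) * params$scale)
    },
    two_component_mixture = {
      need(c("w", "mean1", "sd1", "mean2", "sd2"))
      w <- params$w
      if (w < 0 || w > 1) stop("mixture weight w must be in [0, 1]", call. = FALSE)
      m <- w * params$mean1 + (1 - w) * params$mean2
      m2 <- w * (params$mean1^2 + params$sd1^2) +
        (1 - w) * (params$mean2^2 + params$sd2^2)
      c(m, sqrt(max(m2 - m^2, 0)))
    }
  )
  structure(list(family = family, params = params,
                 mu = mom[1], sigma = mom[2]),
            class = "dfe_spec")
}

#' Sample single-mutation effects from a DFE specification
#'
#' @param spec a [dfe_spec()].
#' @param n number of effects to draw.
#' @return Numeric vector of length `n`.
#' @export
sample_dfe <- function(spec, n) {
  stopifnot(inherits(spec, "dfe_spec"), n >= 0)
  if (n == 0) return(numeric(0))
  p <- spec$params
  switch(spec$family,
    point_mass = rep(p$value, n),
    normal = stats::rnorm(n, p$mean, p$sd),
    gamma_deleterious = -stats::rgamma(n, shape = p$shape, scale = p$scale),
    reflected_gamma = stats::rgamma(n, shape = p$shape, scale = p$scale),
    two_component_mixture = {
      pick <- stats::runif(n) < p$w
      out <- numeric(n)
      out[pick] <- stats::rnorm(sum(pick), p$mean1, p$sd1)
      out[!pick] <- stats::rnorm(sum(!pick), p$mean2, p$sd2)
      out
    }
  )
}

#' @export
print.dfe_spec <- function(x, ...) {
  cat("DFE specification:", x$family, "\n")
  cat("  mu (mean effect):   ", format(x$mu), "\n")
  cat("  sigma (SD of effects):", format(x$sigma), "\n")
  invisible(x)
}
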