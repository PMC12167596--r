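# Descriptive statistics and classical tests on plant-level fitness tables.

#' Group-level summary statistics
#'
#' Per group: number of seedlings, survival rate, and mean/SD of log10 dry
#' weight computed over survivors only (the SD is `NA` with fewer than two
#' survivors).
#'
#' @param table an [experiment_table()].
#' @param grouping `"founder_treatment"` (default) or `"line"` (founder x
#'   line).
#' @return Data frame with columns `founder_id`, (`treatment` or `line_id`),
#'   `n_seedlings`, `survival_rate`, `mean_log10_weight`, `sd_log10_weight`.
#' @export
group_summaries <- function(table,
                            grouping = c("founder_treatment", "line")) {
  stopifnot(inherits(table, "experiment_table"))
  grouping <- match.arg(grouping)
  key2 <- if (grouping == "founder_treatment")
    ifelse(table$ems_treated, "EMS", "control") else table$line_id
  key <- paste(table$founder_id, key2, sep = "\r")
  idx <- split(seq_len(nrow(table)), key)
  out <- do.call(rbind, lapply(names(idx), function(kk) {
    i <- idx[[kk]]
    surv <- table$survived[i]
    lw <- log10(table$dry_weight_mg[i][surv])
    parts <- strsplit(kk, "\r", fixed = TRUE)[[1]]
    data.frame(
      founder_id = parts[1], group = parts[2],
      n_seedlings = length(i),
      survival_rate = mean(surv),
      mean_log10_weight = if (length(lw)) mean(lw) else NA_real_,
      sd_log10_weight = if (length(lw) >= 2) stats::sd(lw) else NA_real_,
      stringsAsFactors = FALSE
    )
  }))
  names(out)[2] <- if (grouping == "founder_treatment") "treatment" else "line_id"
  out <- out[order(out$founder_id, out[[2]]), ]
  rownames(out) <- NULL
  out
}

#' Dunnett-type many-to-one comparison of mutant lines against the control
#'
#' Compares every mutant line of one founder against that founder's control
#' line with family-wise error control, using the exact many-to-one
#' multivariate-t adjustment (via \pkg{multcomp}).  Two passes mirror the
#' two ways of treating seedling mortality: `all_plants` uses the fitness
#' observation of every plant (log10 weight, 0 for non-survivors) and
#' `survivors` uses log10 weight of surviving plants only.
#'
#' @param table an [experiment_table()].
#' @param founder founder label; must have a control line and at least one
#'   mutant line.
#' @param alternative `"greater"` (one-tailed: mutant line outperforms
#'   control; default), `"less"`, or `"two.sided"`.
#' @return List with data frames `all_plants` and `survivors` (columns
#'   `line_id`, `estimate`, `p_adjusted`) and `method` describing the
#'   adjustment.
#' @export
compare_lines_to_control <- function(table, founder,
                                     alternative = c("greater", "less",
                                                     "two.sided")) {
  stopifnot(inherits(table, "experiment_table"))
  alternative <- match.arg(alternative)
  sub <- table[table$founder_id == founder, , drop = FALSE]
  if (!nrow(sub)) stop("no plants for founder ", founder, call. = FALSE)
  has_control <- any(!sub$ems_treated)
  if (!has_control)
    stop("founder ", founder, " has no control line", call. = FALSE)
  mut_lines <- unique(sub$line_id[sub$ems_treated])
  if (!length(mut_lines))
    stop("founder ", founder, " has no mutant lines", call. = FALSE)
  ctrl_label <- unique(sub$line_id[!sub$ems_treated])
  if (length(ctrl_label) > 1)
    stop("multiple control lines for founder ", founder, call. = FALSE)

  one_pass <- function(df, resp) {
    df$line_f <- stats::relevel(factor(df$line_id), ref = ctrl_label)
    df$resp <- resp
    keep <- levels(df$line_f)[table(df$line_f)[levels(df$line_f)] > 0]
    df <- df[df$line_f %in% keep, ]
    df$line_f <- droplevels(df$line_f)
    if (nlevels(df$line_f) < 2) return(NULL)
    fit <- stats::lm(resp ~ line_f, data = df)
    gh <- multcomp::glht(fit, linfct = multcomp::mcp(line_f = "Dunnett"),
                         alternative = alternative)
    sm <- summary(gh)
    data.frame(
      line_id = sub("^line_f", "", names(sm$test$coefficients)),
      estimate = unname(sm$test$coefficients),
      p_adjusted = unname(sm$test$pvalues),
      stringsAsFactors = FALSE
    )
  }
  all_plants <- one_pass(sub, fitness_observation(sub))
  if (!is.null(all_plants))
    all_plants$line_id <- sub(" - .*$", "", all_plants$line_id)
  svs <- sub[sub$survived, , drop = FALSE]
  survivors <- if (any(!svs$ems_treated) && any(svs$ems_treated))
    one_pass(svs, log10(svs$dry_weight_mg)) else NULL
  if (!is.null(survivors))
    survivors$line_id <- sub(" - .*$", "", survivors$line_id)
  list(all_plants = all_plants, survivors = survivors,
       method = "Dunnett many-to-one multivariate-t adjustment (single-step)",
       alternative = alternative, control = ctrl_label)
}

#' Fisher's exact test on two albino silique counts
#'
#' Two-sided exact test of equality of two binomial proportions from a 2x2
#' table, computed by direct hypergeometric enumeration: conditioning on
#' both margins, the first cell `k` follows a hypergeometric distribution,
#' and the p-value sums the probabilities of all tables at most as probable
#' as the observed one (with a 1e-7 relative tolerance on ties).
#'
#' @param a albino (success) count in group A.
#' @param n_a total count in group A.
#' @param b albino count in group B.
#' @param n_b total count in group B.
#' @return List with `p_value`, `estimate` (the two proportions), and
#'   `table` (the 2x2 matrix).
#' @export
albino_fisher_test <- function(a, n_a, b, n_b) {
  counts <- c(a, n_a, b, n_b)
  if (any(counts < 0) || any(counts != as.integer(counts)) ||
      a > n_a || b > n_b)
    stop("counts must be non-negative integers with a <= n_a, b <= n_b",
         call. = FALSE)
  K <- a + b                      # total successes
  N <- n_a + n_b
  support <- max(0, K - n_b):min(n_a, K)
  prob <- choose(K, support) * choose(N - K, n_a - support) / choose(N, n_a)
  p_obs <- prob[support == a]
  p <- sum(prob[prob <= p_obs * (1 + 1e-7)])
  list(p_value = min(p, 1),
       estimate = c(prop_a = a / n_a, prop_b = b / n_b),
       table = matrix(c(a, n_a - a, b, n_b - b), nrow = 2,
                      dimnames = list(c("albino", "normal"), c("A", "B"))))
}

#' Count mutant lines whose mean fitness exceeds the control line's
#'
#' Mean fitness per line is the average fitness observation (log10 weight,
#' 0 for non-survivors) so seedling mortality drags a line's mean down, as
#' in the zero-inflated fitness measure; `include_zeros = FALSE` restricts
#' to survivors' log10 weights instead.
#'
#' @param table an [experiment_table()].
#' @param founder founder label with a control line.
#' @param include_zeros include dead plants as zeros (default `TRUE`).
#' @return List with `n_above`, `n_lines`, and `per_line` (data frame of
#'   line means).
#' @export
count_lines_above_control <- function(table, founder, include_zeros = TRUE) {
  stopifnot(inherits(table, "experiment_table"))
  sub <- table[table$founder_id == founder, , drop = FALSE]
  if (!any(!sub$ems_treated))
    stop("founder ", founder, " has no control line", call. = FALSE)
  if (!include_zeros) sub <- sub[sub$survived, , drop = FALSE]
  val <- if (include_zeros) fitness_observation(sub) else
    log10(sub$dry_weight_mg)
  means <- tapply(val, sub$line_id, mean)
  ctrl <- unique(sub$line_id[!sub$ems_treated])
  mut <- setdiff(names(means), ctrl)
  per_line <- data.frame(line_id = names(means), mean_fitness = as.vector(means),
                         stringsAsFactors = FALSE)
  list(n_above = sum(means[mut] > means[[ctrl]]),
       n_lines = length(mut),
       control_mean = means[[ctrl]],
       per_line = per_line)
}
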