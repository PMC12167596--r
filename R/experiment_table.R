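# Plant-level data model shared by real and synthetic data.
#
# One row per plant: founder, line ("control" or mutant line label), subline,
# spatial block, EMS treatment flag, survival, and dry weight in mg (exactly
# 0 for plants that did not survive).  Dry weight is stored in raw mg; the
# log10 transform is always computed on the fly, never stored, so a table
# can hold zeros without ambiguity.

.et_columns <- c("founder_id", "line_id", "subline_id", "block_id",
                 "ems_treated", "survived", "dry_weight_mg")

#' Construct and validate an experiment table
#'
#' @param df data frame with columns `founder_id`, `line_id`, `subline_id`,
#'   `block_id` (character or factor), `ems_treated`, `survived` (logical),
#'   and `dry_weight_mg` (non-negative numeric, 0 iff not survived).
#' @return The validated data frame with class `experiment_table`.
#' @export
experiment_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.et_columns, names(df))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  df <- df[, .et_columns]
  for (col in c("founder_id", "line_id", "subline_id", "block_id"))
    df[[col]] <- as.character(df[[col]])
  df$ems_treated <- as.logical(df$ems_treated)
  df$survived <- as.logical(df$survived)
  df$dry_weight_mg <- as.numeric(df$dry_weight_mg)
  validate_experiment_table(df)
  class(df) <- c("experiment_table", "data.frame")
  df
}

#' Validate the structural invariants of plant-level fitness data
#'
#' Checks, with row-indexed diagnostics: no missing values in label or flag
#' columns; dry weight non-negative and non-missing; dead plants have weight
#' exactly 0; surviving plants have weight strictly positive; each line is
#' uniformly EMS-treated or uniformly control; EMS lines occur only in
#' founders that also have control plants is \emph{not} required (a table
#' may be subset), but a founder must never mix treatments within a line.
#'
#' @param df data frame with the experiment-table columns.
#' @return Invisibly `TRUE`; stops with an informative message listing the
#'   offending rows otherwise.
#' @export
validate_experiment_table <- function(df) {
  problems <- character(0)
  rows <- function(idx) paste(utils::head(which(idx), 5), collapse = ", ")
  for (col in c("founder_id", "line_id", "subline_id", "block_id",
                "ems_treated", "survived")) {
    bad <- is.na(df[[col]])
    if (any(bad))
      problems <- c(problems, sprintf("missing %s in row(s) %s", col, rows(bad)))
  }
  bad <- is.na(df$dry_weight_mg) | df$dry_weight_mg < 0
  if (any(bad))
    problems <- c(problems,
                  sprintf("missing or negative dry_weight_mg in row(s) %s", rows(bad)))
  ok <- !is.na(df$survived) & !is.na(df$dry_weight_mg) & df$dry_weight_mg >= 0
  bad <- ok & !df$survived & df$dry_weight_mg != 0
  if (any(bad))
    problems <- c(problems,
                  sprintf("dead plant with nonzero weight in row(s) %s", rows(bad)))
  bad <- ok & df$survived & df$dry_weight_mg <= 0
  if (any(bad))
    problems <- c(problems,
                  sprintf("surviving plant with zero weight in row(s) %s", rows(bad)))
  grp <- interaction(df$founder_id, df$line_id, drop = TRUE)
  mixed <- tapply(df$ems_treated, grp, function(x) length(unique(x)) > 1)
  if (any(mixed, na.rm = TRUE))
    problems <- c(problems,
                  sprintf("line(s) mixing EMS and control plants: %s",
                          paste(utils::head(names(mixed)[which(mixed)], 5),
                                collapse = ", ")))
  if (length(problems))
    stop("invalid experiment table:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  invisible(TRUE)
}

#' Log10 fitness observation vector
#'
#' The observation used throughout the analysis: log10 dry weight for
#' survivors and exactly 0 for plants that did not survive.
#'
#' @param table an [experiment_table()].
#' @return Numeric vector, one value per plant.
#' @export
fitness_observation <- function(table) {
  ifelse(table$survived, log10(table$dry_weight_mg), 0)
}

#' Read a plant-level fitness table from delimited text
#'
#' @param path file path.
#' @param delim field delimiter (default comma).
#' @param col_map optional named character vector mapping the canonical
#'   column names to the names used in the file, e.g.
#'   `c(dry_weight_mg = "weight")`.
#' @return An [experiment_table()].
#' @export
read_experiment_table <- function(path, delim = ",", col_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          stringsAsFactors = FALSE, colClasses = "character",
                          check.names = FALSE)
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      if (!col_map[[canon]] %in% names(df))
        stop("mapped column not in file: ", col_map[[canon]], call. = FALSE)
      names(df)[names(df) == col_map[[canon]]] <- canon
    }
  }
  missing_cols <- setdiff(.et_columns, names(df))
  if (length(missing_cols))
    stop("file lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df$ems_treated <- as.logical(df$ems_treated)
  df$survived <- as.logical(df$survived)
  df$dry_weight_mg <- as.numeric(df$dry_weight_mg)
  experiment_table(df)
}

#' Write a plant-level fitness table as delimited text
#'
#' Weights are serialized with 17 significant digits so that a write/read
#' round trip reproduces the numeric values bit for bit.
#'
#' @param table an [experiment_table()].
#' @param path output file path.
#' @param delim field delimiter (default comma).
#' @return Invisibly `path`.
#' @export
write_experiment_table <- function(table, path, delim = ",") {
  stopifnot(inherits(table, "experiment_table"))
  out <- as.data.frame(table)
  out$ems_treated <- ifelse(out$ems_treated, "TRUE", "FALSE")
  out$survived <- ifelse(out$survived, "TRUE", "FALSE")
  out$dry_weight_mg <- sprintf("%.17g", out$dry_weight_mg)
  ok <- tryCatch({
    utils::write.table(out, path, sep = delim, row.names = FALSE,
                       quote = FALSE)
    TRUE
  }, error = function(e) {
    stop("cannot write to ", path, ": ", conditionMessage(e), call. = FALSE)
  })
  invisible(path)
}

#' Per-founder, per-treatment design counts
#'
#' @param table an [experiment_table()].
#' @return Data frame with one row per (founder, treatment): `founder_id`,
#'   `treatment` ("control"/"EMS"), `n_lines`, `n_seedlings`.
#' @export
design_counts <- function(table) {
  stopifnot(inherits(table, "experiment_table"))
  treatment <- ifelse(table$ems_treated, "EMS", "control")
  key <- paste(table$founder_id, treatment, sep = "\r")
  n_seedlings <- as.vector(table(key))
  n_lines <- tapply(table$line_id, key, function(x) length(unique(x)))
  keys <- names(n_lines)
  parts <- strsplit(keys, "\r", fixed = TRUE)
  out <- data.frame(
    founder_id = vapply(parts, `[[`, "", 1),
    treatment = vapply(parts, `[[`, "", 2),
    n_lines = as.integer(n_lines),
    n_seedlings = as.integer(n_seedlings[match(keys, names(table(key)))]),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$founder_id, out$treatment), ]
  rownames(out) <- NULL
  out
}

#' @export
print.experiment_table <- function(x, ...) {
  cat("Experiment table:", nrow(x), "plants,",
      length(unique(x$founder_id)), "founder(s),",
      length(unique(x$block_id)), "block(s)\n")
  NextMethod()
}
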