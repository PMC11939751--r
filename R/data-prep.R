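#' Reverse-code the scoring direction of flagged items
#'
#' Items whose raw coding runs opposite to the construct (autonomy, sleep
#' quality and job satisfaction in the default roster) are flipped so that
#' higher scores mean more of the construct: `v' = (k + 1) - v` for a
#' 1..`k` rating scale. Applying the function twice restores the original
#' table.
#'
#' @param table A `survey_table`.
#' @return The table with reverse-coded ordinal items flipped.
#' @export
reverse_code <- function(table) {
  specs <- attr(table, "specs")
  flipped <- character(0)
  for (s in specs) {
    if (!isTRUE(s$reverse_coded) || s$kind != "ordinal") next
    v <- table[[s$name]]
    bad <- !is.na(v) & (v < 1 | v > s$levels | v != round(v))
    if (any(bad)) {
      stop("'", s$name, "' has values outside its declared 1..",
           s$levels, " level set")
    }
    table[[s$name]] <- (s$levels + 1) - v
    flipped <- c(flipped, s$name)
  }
  log_transform(table, paste0("reverse_code(", paste(flipped, collapse = ","), ")"))
}

#' Drop high-missingness variables, then incomplete rows
#'
#' Variables whose missing fraction exceeds `threshold` are removed; the
#' remaining rows with any missing value are then deleted listwise. Both
#' counts are appended to the transform log.
#'
#' @param table A `survey_table`.
#' @param threshold Missing-fraction cutoff in (0, 1); default 0.10, with
#'   0.05 as the stricter robustness variant.
#' @param outcome Name of the outcome variable, which may never be dropped.
#' @return The filtered table.
#' @export
filter_missing_variables <- function(table, threshold = 0.10, outcome = "Jobs") {
  stopifnot(threshold > 0, threshold < 1)
  frac <- vapply(table, function(v) mean(is.na(v)), numeric(1))
  if (!is.na(frac[outcome]) && frac[outcome] > threshold) {
    stop("outcome variable '", outcome, "' exceeds the missingness threshold (",
         round(frac[outcome], 3), " > ", threshold, ")")
  }
  drop <- names(frac)[frac > threshold]
  keep_cols <- setdiff(names(table), drop)
  specs <- attr(table, "specs")
  out <- table[, keep_cols, drop = FALSE]
  complete <- stats::complete.cases(out)
  out <- out[complete, , drop = FALSE]
  rownames(out) <- NULL
  out <- new_survey_table(out, specs[keep_cols], attr(table, "transforms"))
  log_transform(out, sprintf(
    "filter_missing_variables(threshold=%g): dropped %d variable(s) [%s], %d incomplete row(s)",
    threshold, length(drop), paste(drop, collapse = ","), sum(!complete)))
}

#' Remove rows with infeasible work time
#'
#' Rows reporting more than 84 h of work per week (equivalently, an
#' encoding implying 24 h or more per day over a short week) are removed;
#' 84 h exactly is retained.
#'
#' @param table A `survey_table`.
#' @param variable Weekly work-time column name.
#' @return The filtered table (possibly empty; the removal count is logged).
#' @export
remove_outliers <- function(table, variable = "workt") {
  if (!variable %in% names(table)) {
    stop("no weekly work-time column '", variable, "'")
  }
  bad <- !is.na(table[[variable]]) & table[[variable]] > 84
  out <- table[!bad, , drop = FALSE]
  rownames(out) <- NULL
  out <- new_survey_table(out, attr(table, "specs"), attr(table, "transforms"))
  log_transform(out, sprintf("remove_outliers(%s>84): removed %d row(s)",
                             variable, sum(bad)))
}

#' Dichotomize an outcome at mean + 1 SD
#'
#' Label 1 for values strictly greater than the sample mean plus one sample
#' standard deviation (the high group), 0 otherwise. A zero-variance vector
#' yields all zeros with a warning.
#'
#' @param values Numeric vector without missing values.
#' @return Integer 0/1 labels.
#' @export
dichotomize_outcome <- function(values) {
  stopifnot(!anyNA(values))
  s <- stats::sd(values)
  if (is.na(s) || s == 0) {
    warning("outcome has zero variance; all labels set to 0")
    return(integer(length(values)))
  }
  as.integer(values > mean(values) + s)
}

#' Discretize a numeric vector at its empirical terciles
#'
#' Cutpoints are the type-7 empirical 1/3 and 2/3 quantiles; values at or
#' below the lower cutpoint fall in the bottom bin, values above the upper
#' cutpoint in the top bin. Heavy ties that collapse the two cutpoints
#' trigger a warning and every non-top value falls in the bottom bin.
#'
#' @param values Numeric vector without missing values.
#' @return Integer bins 1 (bottom), 2 (middle), 3 (top).
#' @export
discretize_quantiles <- function(values) {
  stopifnot(!anyNA(values))
  q <- stats::quantile(values, c(1 / 3, 2 / 3), type = 7, names = FALSE)
  if (q[1] == q[2]) {
    warning("degenerate tercile cutpoints (heavy ties); middle bin is empty")
  }
  as.integer(1L + (values > q[1]) + (values > q[2]))
}

# per-variable 3-grade discretization used by binarize(): ordinal variables
# by rating levels, continuous by empirical terciles, binary passed through
variable_grades <- function(values, spec) {
  switch(spec$kind,
    ordinal = ordinal_grade(values, spec$levels),
    continuous = discretize_quantiles(values),
    binary = as.integer(values)
  )
}

#' Build the overlapping binary feature matrix
#'
#' Each 3-grade variable contributes four overlapping incremental binaries
#' (`low` = bottom grade, `low_or_med` = at most middle, `med_or_high` = at
#' least middle, `high` = top grade); binary variables contribute their
#' indicator. Every base feature also gets a `NOT_` complement column. The
#' outcome is dichotomized at mean + 1 SD and excluded from the features.
#'
#' Over three grades the complements duplicate base features column-wise
#' (`NOT_low` equals `med_or_high`, `NOT_high` equals `low_or_med`, and
#' `NOT_low_or_med` equals `high`); they are kept so threshold conditions
#' can be written with either polarity, and rule mining deduplicates
#' content-identical columns.
#'
#' @param table A fully prepared `survey_table` (reverse-coded, filtered,
#'   no missing values).
#' @param outcome Outcome variable name (default `"Jobs"`).
#' @return An object of class `binary_features`: list with `X` (n x m 0/1
#'   integer matrix), `y` (0/1 labels), and `feature_info` (data.frame
#'   mapping features to variables).
#' @export
binarize <- function(table, outcome = "Jobs") {
  specs <- attr(table, "specs")
  if (!outcome %in% names(table)) stop("outcome '", outcome, "' not in table")
  if (anyNA(as.data.frame(table))) {
    stop("table still contains missing values; run filter_missing_variables() first")
  }
  y <- dichotomize_outcome(table[[outcome]])

  cols <- list()
  vars <- character(0)
  for (s in specs[setdiff(names(specs), outcome)]) {
    if (!s$name %in% names(table)) next
    v <- table[[s$name]]
    if (s$kind == "binary") {
      cols[[paste0(s$name, "_1")]] <- as.integer(v == 1)
      vars <- c(vars, s$name)
    } else {
      g <- variable_grades(v, s)
      cols[[paste0(s$name, "_low")]] <- as.integer(g == 1L)
      cols[[paste0(s$name, "_low_or_med")]] <- as.integer(g <= 2L)
      cols[[paste0(s$name, "_med_or_high")]] <- as.integer(g >= 2L)
      cols[[paste0(s$name, "_high")]] <- as.integer(g == 3L)
      vars <- c(vars, rep(s$name, 4))
    }
  }
  base <- do.call(cbind, cols)
  colnames(base) <- names(cols)
  negs <- 1L - base
  colnames(negs) <- paste0("NOT_", colnames(base))
  X <- cbind(base, negs)
  structure(list(X = X, y = y,
                 feature_info = data.frame(feature = colnames(X),
                                           variable = rep(vars, 2),
                                           stringsAsFactors = FALSE)),
            class = "binary_features")
}

#' Run the full preparation sequence
#'
#' Reverse coding, the high-missingness variable filter, work-time outlier
#' removal, listwise deletion, and overlapping binarization, in the order
#' the analysis applies them.
#'
#' @param table A raw `survey_table`.
#' @param missing_threshold Variable-level missingness cutoff (0.10
#'   default; 0.05 for the robustness variant).
#' @param outcome Outcome variable name.
#' @return A `binary_features` object with the prepared table attached as
#'   attribute `table`.
#' @export
prepare_survey <- function(table, missing_threshold = 0.10, outcome = "Jobs") {
  t1 <- reverse_code(table)
  t2 <- filter_missing_variables(t1, missing_threshold, outcome = outcome)
  t3 <- remove_outliers(t2)
  bf <- binarize(t3, outcome = outcome)
  attr(bf, "table") <- t3
  bf
}
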