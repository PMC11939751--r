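#' Declare a survey variable
#'
#' A variable spec records everything the generator and the preparation
#' stage need to know about one survey column: its admissible values, its
#' coding direction, and (for simulation) its sampling law.
#'
#' @param name Short column identifier used in the survey table header.
#' @param kind One of `"ordinal"`, `"continuous"`, `"binary"`.
#' @param levels For ordinal variables, the number of rating levels `k`
#'   (admissible values `1:k`). For binary variables the admissible values
#'   are `c(0, 1)` and `levels` is ignored.
#' @param range For continuous variables, `c(lo, hi)` bounds.
#' @param reverse_coded Logical; `TRUE` when the raw coding runs opposite to
#'   the construct (higher raw value = less of the construct) and must be
#'   flipped by [reverse_code()].
#' @param dist Sampling law, a list with element `type`:
#'   * `"categorical"`: `probs`, a probability vector over `1:k`
#'     (on the construct/analysis scale for reverse-coded variables);
#'   * `"truncnorm"`: `mean`, `sd`, truncated to `range`;
#'   * `"lognormal"`: `meanlog`, `sdlog`, truncated to `range`;
#'   * `"bernoulli"`: `prob` of value 1.
#' @return An object of class `variable_spec`.
#' @export
variable_spec <- function(name, kind = c("ordinal", "continuous", "binary"),
                          levels = NULL, range = NULL,
                          reverse_coded = FALSE, dist = NULL) {
  kind <- match.arg(kind)
  if (kind == "ordinal" && (is.null(levels) || levels < 2)) {
    stop("ordinal variable '", name, "' needs >= 2 levels")
  }
  if (kind == "continuous" && (is.null(range) || length(range) != 2)) {
    stop("continuous variable '", name, "' needs a range c(lo, hi)")
  }
  if (kind == "ordinal" && !is.null(dist) && dist$type == "categorical") {
    if (length(dist$probs) != levels) {
      stop("probability vector for '", name, "' must have ", levels, " entries")
    }
    if (abs(sum(dist$probs) - 1) > 1e-8) {
      stop("probabilities for '", name, "' must sum to 1")
    }
  }
  structure(
    list(name = name, kind = kind, levels = levels, range = range,
         reverse_coded = reverse_coded, dist = dist),
    class = "variable_spec"
  )
}

#' Default variable roster of the job-satisfaction survey
#'
#' The 18 variables of the CGSS-2021 resident-questionnaire extract used in
#' the analysis, with their original codings (ordinal rating scales,
#' continuous hours/minutes/yuan, 0/1 indicators) and simulation
#' distributions calibrated to the published descriptive statistics
#' (e.g. work time mean 48.35 h sd 17.1 truncated to 0--84, income
#' right-skewed log-normal, sleep quality concentrated at the low end).
#' Reverse-coded items are autonomy (`Selfd`), sleep quality (`Sleepq`) and
#' the outcome job satisfaction (`Jobs`).
#'
#' @return A named list of [variable_spec()] objects, class `survey_spec`.
#' @export
default_survey_spec <- function() {
  specs <- list(
    variable_spec("Jobs", "ordinal", levels = 5, reverse_coded = TRUE,
                  dist = list(type = "categorical",
                              probs = c(0.18, 0.42, 0.40, 0, 0))),
    variable_spec("workt", "continuous", range = c(0, 84),
                  dist = list(type = "truncnorm", mean = 48.35, sd = 17.06)),
    variable_spec("Selfd", "ordinal", levels = 4, reverse_coded = TRUE,
                  dist = list(type = "categorical",
                              probs = c(0.15, 0.45, 0.28, 0.12))),
    variable_spec("Workf", "ordinal", levels = 5,
                  dist = list(type = "categorical",
                              probs = c(0.10, 0.15, 0.25, 0.30, 0.20))),
    variable_spec("Famw", "ordinal", levels = 5,
                  dist = list(type = "categorical",
                              probs = c(0.10, 0.12, 0.23, 0.30, 0.25))),
    variable_spec("Roadt", "continuous", range = c(0, 480),
                  dist = list(type = "lognormal", meanlog = 2.71, sdlog = 1.1)),
    variable_spec("income", "continuous", range = c(0, 1500000),
                  dist = list(type = "lognormal", meanlog = 10.43, sdlog = 1.3)),
    variable_spec("class", "ordinal", levels = 10,
                  dist = list(type = "categorical",
                              probs = local({
                                p <- stats::dnorm(1:10, mean = 4.5, sd = 1.65)
                                p / sum(p)
                              }))),
    variable_spec("fair", "ordinal", levels = 5,
                  dist = list(type = "categorical",
                              probs = c(0.10, 0.15, 0.30, 0.33, 0.12))),
    variable_spec("Trusto", "ordinal", levels = 5,
                  dist = list(type = "categorical",
                              probs = c(0.10, 0.12, 0.28, 0.35, 0.15))),
    variable_spec("Sleepq", "ordinal", levels = 4, reverse_coded = TRUE,
                  dist = list(type = "categorical",
                              probs = c(0.17, 0.65, 0.15, 0.03))),
    variable_spec("sleept", "continuous", range = c(6, 12),
                  dist = list(type = "truncnorm", mean = 7.44, sd = 0.94)),
    variable_spec("marry", "binary", dist = list(type = "bernoulli", prob = 0.77)),
    variable_spec("gender", "binary", dist = list(type = "bernoulli", prob = 0.502)),
    variable_spec("Partj", "binary", dist = list(type = "bernoulli", prob = 0.071)),
    variable_spec("age", "continuous", range = c(18, 65),
                  dist = list(type = "truncnorm", mean = 40.07, sd = 11.44)),
    variable_spec("edul", "ordinal", levels = 5,
                  dist = list(type = "categorical",
                              probs = c(0.117, 0.393, 0.055, 0.134, 0.301))),
    variable_spec("health", "ordinal", levels = 5,
                  dist = list(type = "categorical",
                              probs = c(0.12, 0.15, 0.28, 0.30, 0.15)))
  )
  names(specs) <- vapply(specs, function(s) s$name, character(1))
  structure(specs, class = "survey_spec")
}

#' Map ordinal rating levels to three ordered grades
#'
#' Ordinal variables are discretized by their rating levels: the `k` levels
#' are split into three contiguous grade groups, level `l` mapping to grade
#' `ceiling(3 * l / k)`. A 1--5 scale becomes \{1\}, \{2,3\}, \{4,5\}; a 1--4
#' scale \{1\}, \{2\}, \{3,4\}; a 1--10 ladder \{1..3\}, \{4..6\}, \{7..10\}.
#'
#' @param values Integer rating levels in `1:k`.
#' @param k Number of levels.
#' @return Integer grades in 1..3 (1 = low, 2 = medium, 3 = high).
#' @export
ordinal_grade <- function(values, k) {
  out <- ceiling(3 * values / k)
  out[out < 1L] <- 1L
  as.integer(out)
}

# quantile function of a spec's sampling law (used for theoretical terciles
# and for conditional draws during rule planting)
spec_quantile <- function(spec, p) {
  d <- spec$dist
  switch(d$type,
    truncnorm = {
      lo <- stats::pnorm(spec$range[1], d$mean, d$sd)
      hi <- stats::pnorm(spec$range[2], d$mean, d$sd)
      stats::qnorm(lo + p * (hi - lo), d$mean, d$sd)
    },
    lognormal = {
      lo <- stats::plnorm(spec$range[1], d$meanlog, d$sdlog)
      hi <- stats::plnorm(spec$range[2], d$meanlog, d$sdlog)
      stats::qlnorm(lo + p * (hi - lo), d$meanlog, d$sdlog)
    },
    stop("quantile only defined for continuous sampling laws")
  )
}

# one unconditional draw of n values on the construct (analysis) scale
spec_sample <- function(spec, n) {
  d <- spec$dist
  switch(d$type,
    categorical = sample.int(spec$levels, n, replace = TRUE, prob = d$probs),
    bernoulli   = stats::rbinom(n, 1, d$prob),
    truncnorm   = ,
    lognormal   = spec_quantile(spec, stats::runif(n))
  )
}
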