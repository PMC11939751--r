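#' Declare a planted rule
#'
#' A planted rule is a conjunction of at most three literals over
#' *discretized* variable categories (the same categories the preparation
#' stage exposes as binary features), so that the ground truth is
#' expressible in the mined feature space. Each literal names a variable,
#' one of the overlapping categories `"low"`, `"low_or_med"`,
#' `"med_or_high"`, `"high"` (or `"1"`/`"0"` for binary variables), and an
#' optional negation flag.
#'
#' @param literals A list of literals, each a list with elements `variable`,
#'   `category`, and optionally `negated` (default `FALSE`).
#' @param target_support Optional fraction in (0, 1); when given, the
#'   generator forces the empirical support of the rule towards this value
#'   by conditional resampling.
#' @return An object of class `planted_rule`.
#' @export
planted_rule <- function(literals, target_support = NULL) {
  if (length(literals) < 1 || length(literals) > 3) {
    stop("a planted rule must have 1 to 3 literals")
  }
  literals <- lapply(literals, function(l) {
    if (is.null(l$negated)) l$negated <- FALSE
    stopifnot(!is.null(l$variable), !is.null(l$category))
    l
  })
  if (!is.null(target_support) &&
      (target_support <= 0 || target_support >= 1)) {
    stop("target_support must lie in (0, 1)")
  }
  structure(list(literals = literals, target_support = target_support),
            class = "planted_rule")
}

#' The two headline planted rules
#'
#' The rule structure planted by default in the synthetic study conditions:
#' medium-or-high health AND high autonomy AND low work time; high age AND
#' medium-or-high sleep quality AND low work time.
#'
#' @return A list of two [planted_rule()] objects.
#' @export
headline_rules <- function() {
  list(
    planted_rule(list(
      list(variable = "health", category = "med_or_high"),
      list(variable = "Selfd", category = "high"),
      list(variable = "workt", category = "low")
    )),
    planted_rule(list(
      list(variable = "age", category = "high"),
      list(variable = "Sleepq", category = "med_or_high"),
      list(variable = "workt", category = "low")
    ))
  )
}

#' Simulation configuration
#'
#' @param n Number of respondents.
#' @param seed Integer RNG seed.
#' @param variables A `survey_spec` (default [default_survey_spec()]).
#' @param planted_rules List of [planted_rule()] objects; rows satisfying
#'   any of them get a high outcome with probability `1 - noise_rate`,
#'   all other rows with probability `noise_rate`.
#' @param noise_rate Label-flip probability in `[0, 0.5)`.
#' @param missing_rates Optional named vector of per-variable MCAR rates.
#' @param outlier_rate Fraction of rows given an infeasible weekly work
#'   time (> 84 h).
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n, seed, variables = default_survey_spec(),
                              planted_rules = list(), noise_rate = 0.1,
                              missing_rates = NULL, outlier_rate = 0) {
  stopifnot(n >= 1, is.numeric(seed))
  if (noise_rate < 0 || noise_rate >= 0.5) {
    stop("noise_rate must lie in [0, 0.5)")
  }
  if (!is.null(missing_rates) &&
      (any(missing_rates < 0) || any(missing_rates > 1))) {
    stop("missing rates must lie in [0, 1]")
  }
  if (outlier_rate < 0 || outlier_rate > 1) stop("outlier_rate must lie in [0, 1]")
  for (r in planted_rules) {
    for (l in r$literals) {
      if (!l$variable %in% names(variables)) {
        stop("planted rule references undeclared variable '", l$variable, "'")
      }
    }
  }
  structure(list(n = n, seed = as.integer(seed), variables = variables,
                 planted_rules = planted_rules, noise_rate = noise_rate,
                 missing_rates = missing_rates, outlier_rate = outlier_rate),
            class = "simulation_config")
}

# grade (1..3) of analysis-scale values under a spec; continuous variables
# use the theoretical terciles of their sampling law as cutpoints
value_grade <- function(values, spec) {
  switch(spec$kind,
    ordinal = ordinal_grade(values, spec$levels),
    continuous = {
      q <- spec_quantile(spec, c(1 / 3, 2 / 3))
      as.integer(1L + (values > q[1]) + (values > q[2]))
    },
    binary = as.integer(values)
  )
}

# does a grade / binary value fall in an overlapping category?
category_test <- function(g, category, kind) {
  hit <- if (kind == "binary") {
    g == as.integer(category)
  } else {
    switch(category,
      low = g == 1L, low_or_med = g <= 2L,
      med_or_high = g >= 2L, high = g == 3L,
      stop("unknown category '", category, "'")
    )
  }
  hit
}

literal_test <- function(values, l, spec) {
  hit <- category_test(value_grade(values, spec), l$category, spec$kind)
  if (isTRUE(l$negated)) !hit else hit
}

# marginal probability that a fresh draw satisfies (or violates) a literal
literal_prob <- function(l, spec) {
  p <- switch(spec$kind,
    ordinal = {
      grades <- ordinal_grade(seq_len(spec$levels), spec$levels)
      sum(spec$dist$probs[category_test(grades, l$category, "ordinal")])
    },
    continuous = if (l$category %in% c("low", "high")) 1 / 3 else 2 / 3,
    binary = if (identical(l$category, "1")) spec$dist$prob else 1 - spec$dist$prob
  )
  if (isTRUE(l$negated)) 1 - p else p
}

# draw m values conditional on satisfying (satisfy=TRUE) or violating a literal
literal_conditional_draw <- function(l, spec, m) {
  want <- !isTRUE(l$negated)
  if (spec$kind == "ordinal") {
    grades <- ordinal_grade(seq_len(spec$levels), spec$levels)
    keep <- category_test(grades, l$category, "ordinal") == want
    pr <- spec$dist$probs[keep]
    if (sum(pr) <= 0) return(NULL)
    sample(seq_len(spec$levels)[keep], m, replace = TRUE, prob = pr)
  } else if (spec$kind == "binary") {
    val <- as.integer(identical(l$category, "1"))
    rep(if (want) val else 1L - val, m)
  } else {
    lohi <- switch(l$category,
      low = c(0, 1 / 3), low_or_med = c(0, 2 / 3),
      med_or_high = c(1 / 3, 1), high = c(2 / 3, 1))
    if (!want) {
      # complement of a tercile interval within [0,1]
      if (lohi[1] == 0) lohi <- c(lohi[2], 1) else lohi <- c(0, lohi[1])
    }
    spec_quantile(spec, stats::runif(m, lohi[1], lohi[2]))
  }
}

rule_satisfied_rows <- function(tab, rule, specs) {
  hit <- rep(TRUE, nrow(tab))
  for (l in rule$literals) {
    hit <- hit & literal_test(tab[[l$variable]], l, specs[[l$variable]])
  }
  hit
}

#' Generate a synthetic survey table
#'
#' Samples every variable from its declared law on the construct (analysis)
#' scale, optionally forces planted-rule support towards a target by
#' conditional resampling, assigns the job-satisfaction outcome from the
#' planted OR-of-ANDs structure plus label noise, and finally converts
#' reverse-coded items back to their original survey codings. Rows
#' satisfying any planted rule draw a high outcome (top rating) with
#' probability `1 - noise_rate`; all other rows with probability
#' `noise_rate`.
#'
#' @param config A [simulation_config()].
#' @return A data.frame of class `survey_table` in original codings, with
#'   attributes `specs`, `transforms` (an append-only log), and `generator`
#'   (seed, planted rules, tercile cutpoints of continuous variables, the
#'   true covered indicator and noisy labels).
#' @export
generate_survey <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  specs <- config$variables
  n <- config$n

  tab <- as.data.frame(lapply(specs, function(s) {
    if (s$name == "Jobs") rep(NA_real_, n) else spec_sample(s, n)
  }))
  names(tab) <- names(specs)

  targeted <- Filter(function(r) !is.null(r$target_support), config$planted_rules)
  if (length(targeted)) {
    s <- vapply(targeted, function(r) r$target_support, numeric(1))
    if (sum(s) >= 1) stop("infeasible planted rules: target supports sum to >= 1")
    for (ri in seq_along(targeted)) {
      for (l in targeted[[ri]]$literals) {
        if (literal_prob(l, specs[[l$variable]]) <= 0) {
          stop("planted rule ", ri, " is unsatisfiable: literal on '",
               l$variable, "' (", l$category, ") has zero probability")
        }
      }
    }
    assign_id <- sample.int(length(targeted) + 1L, n, replace = TRUE,
                            prob = c(1 - sum(s), s)) - 1L
    for (ri in seq_along(targeted)) {
      rule <- targeted[[ri]]
      rows <- which(assign_id == ri)
      for (l in rule$literals) {
        draw <- literal_conditional_draw(l, specs[[l$variable]], length(rows))
        if (is.null(draw)) {
          stop("planted rule ", ri, " is unsatisfiable on '", l$variable, "'")
        }
        tab[[l$variable]][rows] <- draw
      }
      # break the rule on rows not assigned to it, preferring literals whose
      # variable is not shared with the row's own assigned rule
      off <- which(assign_id != ri & rule_satisfied_rows(tab, rule, specs))
      for (i in off) {
        own_vars <- if (assign_id[i] > 0) {
          vapply(targeted[[assign_id[i]]]$literals, `[[`, character(1), "variable")
        } else character(0)
        lits <- rule$literals
        free <- Filter(function(l) !(l$variable %in% own_vars), lits)
        if (!length(free)) next  # fully overlapping with the assigned rule
        l <- free[[sample.int(length(free), 1)]]
        l$negated <- !isTRUE(l$negated)
        draw <- literal_conditional_draw(l, specs[[l$variable]], 1L)
        if (!is.null(draw)) tab[[l$variable]][i] <- draw
      }
    }
  }

  covered <- rep(FALSE, n)
  for (rule in config$planted_rules) {
    covered <- covered | rule_satisfied_rows(tab, rule, specs)
  }
  p_high <- ifelse(covered, 1 - config$noise_rate, config$noise_rate)
  y <- stats::rbinom(n, 1, p_high)

  jspec <- specs[["Jobs"]]
  low_probs <- jspec$dist$probs
  low_levels <- which(low_probs > 0)
  jobs <- integer(n)
  jobs[y == 1] <- jspec$levels
  if (any(y == 0)) {
    jobs[y == 0] <- sample(low_levels, sum(y == 0), replace = TRUE,
                           prob = low_probs[low_levels])
  }
  tab$Jobs <- jobs

  # emit original codings: reverse-coded ordinal items are flipped back
  for (s in specs) {
    if (isTRUE(s$reverse_coded) && s$kind == "ordinal") {
      tab[[s$name]] <- (s$levels + 1) - tab[[s$name]]
    }
  }

  cutpoints <- lapply(Filter(function(s) s$kind == "continuous", specs),
                      function(s) spec_quantile(s, c(1 / 3, 2 / 3)))
  out <- new_survey_table(tab, specs,
                          transforms = sprintf("generate_survey(n=%d, seed=%d)",
                                               n, config$seed))
  attr(out, "generator") <- list(seed = config$seed,
                                 noise_rate = config$noise_rate,
                                 planted_rules = config$planted_rules,
                                 cutpoints = cutpoints,
                                 covered = covered, labels = y)
  if (!is.null(config$missing_rates)) {
    out <- inject_missingness(out, config$missing_rates,
                              seed = config$seed + 1L)
  }
  if (config$outlier_rate > 0) {
    out <- inject_outliers(out, config$outlier_rate, seed = config$seed + 2L)
  }
  out
}

new_survey_table <- function(df, specs, transforms = character(0)) {
  structure(df, specs = specs, transforms = transforms,
            class = c("survey_table", "data.frame"))
}

log_transform <- function(table, msg) {
  attr(table, "transforms") <- c(attr(table, "transforms"), msg)
  table
}

#' Inject missing values completely at random
#'
#' @param table A `survey_table`.
#' @param rates Named vector of per-variable missingness probabilities.
#' @param seed RNG seed.
#' @return The table with values replaced by `NA` at the given rates.
#' @export
inject_missingness <- function(table, rates, seed) {
  unknown <- setdiff(names(rates), names(table))
  if (length(unknown)) stop("unknown variable(s): ", paste(unknown, collapse = ", "))
  if (any(rates < 0) || any(rates > 1)) stop("rates must lie in [0, 1]")
  set.seed(seed)
  for (v in names(rates)) {
    if (rates[[v]] == 0) next
    miss <- stats::runif(nrow(table)) < rates[[v]]
    table[[v]][miss] <- NA
  }
  log_transform(table, sprintf("inject_missingness(seed=%d; %s)", seed,
                               paste(names(rates), rates, sep = "=", collapse = ",")))
}

#' Inject infeasible work-time outliers
#'
#' A fraction `rate` of rows gets its weekly work time replaced by a value
#' above 84 h (uniform on 85--168, i.e. up to 24 h/day), emulating the
#' implausible reports removed by [remove_outliers()].
#'
#' @param table A `survey_table` with a `workt` column.
#' @param rate Fraction of rows to contaminate.
#' @param seed RNG seed.
#' @param variable Name of the weekly work-time column.
#' @return The contaminated table.
#' @export
inject_outliers <- function(table, rate, seed, variable = "workt") {
  if (rate < 0 || rate > 1) stop("rate must lie in [0, 1]")
  if (!variable %in% names(table)) stop("no work-time column '", variable, "'")
  set.seed(seed)
  hit <- stats::runif(nrow(table)) < rate
  table[[variable]][hit] <- stats::runif(sum(hit), 85, 168)
  log_transform(table, sprintf("inject_outliers(rate=%g, seed=%d, n_injected=%d)",
                               rate, seed, sum(hit)))
}

#' Write a survey table and its provenance sidecar
#'
#' Writes the table as CSV (header = variable abbreviations) and a JSON
#' sidecar recording the seed, planted rules and tercile cutpoints.
#'
#' @param table A `survey_table`.
#' @param csv_path Output CSV path.
#' @param json_path Output JSON sidecar path (default: CSV path with
#'   `.json` extension).
#' @return Invisibly, the CSV path.
#' @export
write_survey <- function(table, csv_path,
                         json_path = sub("\\.csv$", ".json", csv_path)) {
  utils::write.csv(as.data.frame(table), csv_path, row.names = FALSE)
  gen <- attr(table, "generator")
  side <- list(transforms = attr(table, "transforms"))
  if (!is.null(gen)) {
    side$seed <- gen$seed
    side$noise_rate <- gen$noise_rate
    side$cutpoints <- gen$cutpoints
    side$planted_rules <- lapply(gen$planted_rules, function(r) {
      list(target_support = r$target_support,
           literals = lapply(r$literals, function(l) {
             list(variable = l$variable, category = l$category,
                  negated = isTRUE(l$negated))
           }))
    })
  }
  jsonlite::write_json(side, json_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(csv_path)
}
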