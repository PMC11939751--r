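#' Bootstrap stability of the fitted rule set
#'
#' Draws `B` bootstrap resamples (with replacement, size n), re-mines the
#' candidate pool and re-fits the rule set on each, and summarizes every
#' rule that ever enters a MAP set: its prevalence (fraction of resamples
#' whose MAP set contains it, with rule identity = exact canonical literal
#' set), its mean true-positive and false-positive coverage on the
#' resamples where it appears (in-bag by default), and the 2.5th/97.5th
#' percentiles of its signed coverage (TP minus FP). Rules with prevalence
#' at or above `prevalence_threshold` form the aggregated rule set.
#'
#' @param features A `binary_features` object or 0/1 matrix.
#' @param labels 0/1 labels.
#' @param pool_config A [mining_config()].
#' @param fit_config A [brs_chains()] (its seed is overridden per resample).
#' @param prior,lik Prior and likelihood settings.
#' @param B Number of bootstrap resamples (default 100).
#' @param seed Master seed for resampling and chain seeds.
#' @param prevalence_threshold Aggregation cutoff (default 0.05, i.e. a
#'   rule kept when appearing in at least 5 of 100 resamples).
#' @param out_of_bag If `TRUE`, coverage is evaluated on the rows left out
#'   of each resample instead of in-bag.
#' @return An object of class `stability_report`: data.frame `rules` (rule,
#'   prevalence, tp_coverage, fp_coverage signed negative, ci_low,
#'   ci_high), `aggregated` (list of rules), `B`, `seed`.
#' @export
bootstrap_stability <- function(features, labels = NULL,
                                pool_config = mining_config(),
                                fit_config = brs_chains(),
                                prior = brs_prior(), lik = brs_likelihood(),
                                B = 100, seed = 1,
                                prevalence_threshold = 0.05,
                                out_of_bag = FALSE) {
  stopifnot(B >= 1)
  X <- feature_matrix(features)
  if (is.null(labels) && inherits(features, "binary_features")) {
    labels <- features$y
  }
  n <- nrow(X)
  y <- as.integer(labels == 1)

  set.seed(seed)
  resample_idx <- lapply(seq_len(B), function(b) sample.int(n, n, replace = TRUE))
  chain_seeds <- sample.int(.Machine$integer.max - 1L, B)

  hits <- list()   # per rule string: list of c(tp, fp) per appearing resample
  for (b in seq_len(B)) {
    idx <- resample_idx[[b]]
    Xb <- X[idx, , drop = FALSE]
    yb <- y[idx]
    pool <- suppressWarnings(mine_candidates(Xb, yb, pool_config))
    if (!nrow(pool)) next
    cfg <- fit_config
    cfg$seed <- chain_seeds[b]
    fit <- brs_fit(Xb, yb, pool, prior = prior, lik = lik, chains = cfg)
    if (out_of_bag) {
      oob <- setdiff(seq_len(n), unique(idx))
      Xe <- X[oob, , drop = FALSE]; ye <- y[oob]
    } else {
      Xe <- Xb; ye <- yb
    }
    for (r in fit$map_rules) {
      key <- rule_string(r)
      cf <- coverage_decomposition(r, Xe, ye)
      hits[[key]] <- c(hits[[key]], list(cf))
    }
  }

  if (!length(hits)) {
    warning("all resamples produced an empty MAP rule set")
    rules_df <- data.frame(rule = character(0), prevalence = numeric(0),
                           tp_coverage = numeric(0), fp_coverage = numeric(0),
                           ci_low = numeric(0), ci_high = numeric(0))
  } else {
    rules_df <- do.call(rbind, lapply(names(hits), function(key) {
      tp <- vapply(hits[[key]], `[[`, numeric(1), "tp")
      fp <- vapply(hits[[key]], `[[`, numeric(1), "fp")
      signed <- tp - fp
      ci <- stats::quantile(signed, c(0.025, 0.975), type = 7, names = FALSE)
      data.frame(rule = key, prevalence = length(tp) / B,
                 tp_coverage = mean(tp), fp_coverage = -mean(fp),
                 ci_low = ci[1], ci_high = ci[2], stringsAsFactors = FALSE)
    }))
    rules_df <- rules_df[order(-rules_df$prevalence, rules_df$rule), ,
                         drop = FALSE]
    rownames(rules_df) <- NULL
  }
  aggregated <- lapply(rules_df$rule[rules_df$prevalence >= prevalence_threshold],
                       parse_rule)
  structure(list(rules = rules_df, aggregated = aggregated, B = B,
                 seed = seed, prevalence_threshold = prevalence_threshold),
            class = "stability_report")
}

#' True/false-positive coverage of one rule
#'
#' @param rule A rule (literal vector or `"a&b"` string).
#' @param features A `binary_features` object or 0/1 matrix.
#' @param labels 0/1 labels.
#' @return A list with `tp` (covered rows with label 1) and `fp` (covered
#'   rows with label 0; reported as a negative contribution in outputs).
#' @export
coverage_decomposition <- function(rule, features, labels = NULL) {
  if (is.null(labels) && inherits(features, "binary_features")) {
    labels <- features$y
  }
  cov <- rule_cover(rule, features)
  list(tp = sum(cov == 1L & labels == 1), fp = sum(cov == 1L & labels == 0))
}

#' Per-row classification outcome labels
#'
#' Confusion label of every row under a rule set's OR-of-ANDs prediction,
#' as exported for embedding/plotting tools: TP, TN, FP, FN.
#'
#' @param rules List of rules (or a `brs_fit`).
#' @param features A `binary_features` object or 0/1 matrix.
#' @param labels 0/1 labels.
#' @return Factor of length n with levels TP, TN, FP, FN.
#' @export
classification_outcomes <- function(rules, features, labels = NULL) {
  if (is.null(labels) && inherits(features, "binary_features")) {
    labels <- features$y
  }
  pred <- brs_predict(rules, features)
  out <- ifelse(pred == 1 & labels == 1, "TP",
         ifelse(pred == 0 & labels == 0, "TN",
         ifelse(pred == 1 & labels == 0, "FP", "FN")))
  factor(out, levels = c("TP", "TN", "FP", "FN"))
}

# variable behind a feature name: strip NOT_ prefix and category suffix
feature_variable <- function(feature) {
  v <- sub("^(!|NOT_)+", "", feature)
  sub("_(low_or_med|med_or_high|low|high|1)$", "", v)
}

#' Variable co-occurrence edges of an aggregated rule set
#'
#' For each unordered pair of variables, the weight is the number of
#' aggregated rules in which both appear (the chord-diagram edge list;
#' rendering is out of scope).
#'
#' @param report A `stability_report`, `brs_fit`, or plain list of rules.
#' @return data.frame with columns `var1`, `var2`, `weight`.
#' @export
interaction_edges <- function(report) {
  rules <- if (inherits(report, "stability_report")) report$aggregated
    else if (inherits(report, "brs_fit")) report$map_rules
    else report
  counts <- list()
  for (r in rules) {
    vars <- sort(unique(feature_variable(parse_rule(r))))
    if (length(vars) < 2) next
    pr <- utils::combn(vars, 2)
    for (j in seq_len(ncol(pr))) {
      key <- paste(pr[1, j], pr[2, j], sep = "\t")
      counts[[key]] <- (counts[[key]] %||% 0) + 1
    }
  }
  if (!length(counts)) {
    return(data.frame(var1 = character(0), var2 = character(0),
                      weight = numeric(0)))
  }
  parts <- strsplit(names(counts), "\t", fixed = TRUE)
  out <- data.frame(var1 = vapply(parts, `[[`, character(1), 1),
                    var2 = vapply(parts, `[[`, character(1), 2),
                    weight = unlist(counts), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(-out$weight, out$var1, out$var2), , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize a stability report
#'
#' TSV with one row per rule (literals, prevalence, tp, -fp, ci bounds)
#' plus a JSON with the aggregated set.
#'
#' @param report A `stability_report`.
#' @param tsv_path,json_path Output paths.
#' @return Invisibly, `tsv_path`.
#' @export
write_stability_report <- function(report, tsv_path,
                                   json_path = sub("\\.tsv$", ".json", tsv_path)) {
  utils::write.table(report$rules, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(
    list(aggregated = lapply(report$aggregated, as.list), B = report$B,
         seed = report$seed,
         prevalence_threshold = report$prevalence_threshold),
    json_path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(tsv_path)
}
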