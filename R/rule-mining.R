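#' Mining configuration
#'
#' @param max_len Maximum number of literals per rule (default 3).
#' @param min_support Minimum fraction of all rows a rule must cover
#'   (default 0.05); the count threshold is `ceiling(min_support * n)`
#'   ("at least 5% of the data").
#' @param max_rules Pool cap (default 5000); when the enumeration exceeds
#'   it, rules are ranked by information gain towards the positive class
#'   and truncated.
#' @param class_conditional If `TRUE`, support is computed over the
#'   positive class only instead of all rows.
#' @return An object of class `mining_config`.
#' @export
mining_config <- function(max_len = 3, min_support = 0.05, max_rules = 5000,
                          class_conditional = FALSE) {
  stopifnot(max_len >= 1, min_support > 0, min_support < 1, max_rules >= 1)
  structure(list(max_len = max_len, min_support = min_support,
                 max_rules = max_rules, class_conditional = class_conditional),
            class = "mining_config")
}

feature_matrix <- function(features) {
  if (inherits(features, "binary_features")) features$X else as.matrix(features)
}

#' Indicator vector of a conjunctive rule
#'
#' A rule covers a row when the row satisfies every literal (AND logic).
#' Literals are feature-column names; a `"!"` prefix denotes the logical
#' complement of a column (used by extracted decision-tree rules when no
#' explicit `NOT_` column exists).
#'
#' @param rule Character vector of literals, or a single `"a&b&c"` string.
#' @param features A `binary_features` object or a 0/1 matrix with column
#'   names.
#' @return Integer 0/1 vector of length `nrow(features)`.
#' @export
rule_cover <- function(rule, features) {
  X <- feature_matrix(features)
  lits <- parse_rule(rule)
  if (length(lits) == 0) stop("empty conjunctions are not allowed")
  out <- rep(1L, nrow(X))
  for (l in lits) {
    neg <- startsWith(l, "!")
    nm <- sub("^!", "", l)
    if (!nm %in% colnames(X)) stop("unknown literal '", nm, "'")
    col <- X[, nm]
    out <- out * (if (neg) 1L - col else col)
  }
  as.integer(out)
}

parse_rule <- function(rule) {
  if (length(rule) == 1 && grepl("&", rule, fixed = TRUE)) {
    strsplit(rule, "&", fixed = TRUE)[[1]]
  } else {
    as.character(rule)
  }
}

rule_string <- function(literals) paste(sort(literals), collapse = "&")

# binary entropy in nats, vectorized over counts
entropy2 <- function(pos, tot) {
  p <- pos / tot
  h <- numeric(length(p))
  ok <- tot > 0 & p > 0 & p < 1
  h[ok] <- -(p[ok] * log(p[ok]) + (1 - p[ok]) * log(1 - p[ok]))
  h
}

# information gain of splitting labels by a cover indicator, from counts
info_gain <- function(n, npos, cov, tp) {
  h0 <- entropy2(npos, n)
  hin <- entropy2(tp, cov)
  hout <- entropy2(npos - tp, n - cov)
  h0 - (cov / n) * hin - ((n - cov) / n) * hout
}

# a conjunction is extensionally redundant when its cover equals the cover
# of one of its sub-rules (e.g. a literal implied by another, as with the
# nested overlapping categories); such rules duplicate a shorter rule and
# are dropped from the pool

#' Mine the candidate rule pool
#'
#' Enumerates all conjunctions of up to `max_len` distinct binary features
#' with support at least `ceiling(min_support * n)` rows, excluding
#' internally contradictory combinations (a feature together with its
#' column-wise complement). Content-identical feature columns are
#' deduplicated first (keeping the first name) so synonymous encodings
#' yield one canonical rule, and conjunctions whose cover equals that of
#' one of their sub-rules (a literal implied by another, as with nested
#' overlapping categories) are dropped as extensional duplicates of the
#' shorter rule. When the pool exceeds `max_rules`, rules are
#' ranked by information gain with respect to the labels and truncated.
#'
#' @param features A `binary_features` object or 0/1 matrix.
#' @param labels 0/1 outcome labels (taken from the `binary_features`
#'   object when omitted).
#' @param config A [mining_config()].
#' @return A data.frame of class `rule_pool` with columns `rule`, `length`,
#'   `support` (fraction of rows), `support_n`, `gain`, ordered by length,
#'   then decreasing gain, then rule string. Empty (with a warning) when no
#'   rule meets the support threshold.
#' @export
mine_candidates <- function(features, labels = NULL, config = mining_config()) {
  X <- feature_matrix(features)
  if (is.null(labels) && inherits(features, "binary_features")) {
    labels <- features$y
  }
  stopifnot(!is.null(labels), length(labels) == nrow(X))
  n <- nrow(X)
  base_n <- if (config$class_conditional) sum(labels == 1) else n
  thresh <- ceiling(config$min_support * base_n)

  keep <- !duplicated(t(X))
  X <- X[, keep, drop = FALSE]
  storage.mode(X) <- "double"
  m <- ncol(X)
  y <- as.numeric(labels == 1)
  npos <- sum(y)

  s1 <- colSums(X)
  supp_of <- function(cov_count, pos_count) {
    if (config$class_conditional) pos_count else cov_count
  }
  tp1 <- as.numeric(crossprod(X, y))

  rules <- list()
  add_rules <- function(lit_idx_mat, cov, tp) {
    # lit_idx_mat: one row per rule, column indices of literals
    if (!nrow(lit_idx_mat)) return(invisible())
    strs <- apply(lit_idx_mat, 1, function(ix) rule_string(colnames(X)[ix]))
    rules[[length(rules) + 1]] <<- data.frame(
      rule = strs, length = ncol(lit_idx_mat),
      support = cov / n, support_n = as.integer(cov),
      gain = info_gain(n, npos, cov, tp),
      stringsAsFactors = FALSE)
  }

  ok1 <- which(supp_of(s1, tp1) >= thresh & s1 > 0)
  add_rules(matrix(ok1, ncol = 1), s1[ok1], tp1[ok1])

  # complement pairs (content-based): disjoint and jointly exhaustive
  S2 <- crossprod(X)
  comp <- (S2 == 0) & (outer(s1, s1, `+`) == n)

  pairs <- NULL
  if (config$max_len >= 2 && length(ok1) >= 2) {
    cand <- which(upper.tri(S2) & S2 >= 1 & !comp, arr.ind = TRUE)
    if (nrow(cand)) {
      pc <- S2[cand]
      Xy <- X * y
      # true-positive counts of pairs via one product
      TP2 <- crossprod(X, Xy)
      tp2 <- TP2[cand]
      ok <- supp_of(pc, tp2) >= thresh &
        pc < s1[cand[, 1]] & pc < s1[cand[, 2]]   # drop redundant pairs
      cand <- cand[ok, , drop = FALSE]
      pc <- pc[ok]; tp2 <- tp2[ok]
      add_rules(cand, pc, tp2)
      pairs <- list(idx = cand, cov = pc)
    }
  }

  if (config$max_len >= 3 && !is.null(pairs) && nrow(pairs$idx)) {
    P <- X[, pairs$idx[, 1], drop = FALSE] * X[, pairs$idx[, 2], drop = FALSE]
    S3 <- crossprod(P, X)                 # pair x single joint support
    TP3 <- crossprod(P * y, X)
    # extend pair (i < j) only with singles l > j; forbid complements
    jmax <- pairs$idx[, 2]
    ext <- outer(jmax, seq_len(m), `<`)
    ext <- ext & !comp[pairs$idx[, 1], , drop = FALSE] &
      !comp[pairs$idx[, 2], , drop = FALSE]
    hit <- which(ext & S3 >= 1, arr.ind = TRUE)
    if (nrow(hit)) {
      cov3 <- S3[hit]; tp3 <- TP3[hit]
      i <- pairs$idx[hit[, 1], 1]; j <- pairs$idx[hit[, 1], 2]; l <- hit[, 2]
      ok <- supp_of(cov3, tp3) >= thresh &
        cov3 < S2[cbind(i, j)] & cov3 < S2[cbind(i, l)] &
        cov3 < S2[cbind(j, l)]                     # drop redundant triples
      if (any(ok)) {
        add_rules(cbind(i, j, l)[ok, , drop = FALSE], cov3[ok], tp3[ok])
      }
    }
  }

  pool <- if (length(rules)) do.call(rbind, rules) else {
    data.frame(rule = character(0), length = integer(0), support = numeric(0),
               support_n = integer(0), gain = numeric(0))
  }
  if (!nrow(pool)) {
    warning("no rule meets the support threshold; empty pool")
  }
  pool <- pool[order(pool$length, -pool$gain, pool$rule), , drop = FALSE]
  if (nrow(pool) > config$max_rules) {
    ord <- order(-pool$gain, -pool$support, pool$rule)
    pool <- pool[sort(ord[seq_len(config$max_rules)]), , drop = FALSE]
  }
  rownames(pool) <- NULL
  class(pool) <- c("rule_pool", "data.frame")
  attr(pool, "n") <- n
  pool
}

#' Serialize a rule pool as TSV
#'
#' @param pool A `rule_pool`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_rule_pool <- function(pool, path) {
  df <- as.data.frame(pool)
  df$id <- seq_len(nrow(df))
  utils::write.table(df[, c("id", "rule", "length", "support", "gain")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
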