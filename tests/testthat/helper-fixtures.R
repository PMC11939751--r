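# Random binary fixtures and brute-force oracles used across the suite.

# drop survey-table attributes (specs, transform log, generator) so value
# comparisons ignore provenance metadata
plain_df <- function(t) {
  d <- as.data.frame(t)
  out <- data.frame(d, check.names = FALSE)
  attr(out, "specs") <- NULL
  attr(out, "transforms") <- NULL
  attr(out, "generator") <- NULL
  class(out) <- "data.frame"
  rownames(out) <- NULL
  out
}

random_binary_matrix <- function(n, m, seed, p = 0.5, prefix = "f") {
  set.seed(seed)
  X <- matrix(rbinom(n * m, 1, p), n, m,
              dimnames = list(NULL, paste0(prefix, seq_len(m))))
  X
}

random_labels <- function(n, seed, p = 0.4) {
  set.seed(seed)
  rbinom(n, 1, p)
}

# brute-force cover: elementwise product of literal columns
oracle_cover <- function(lits, X) {
  out <- rep(1L, nrow(X))
  for (l in lits) {
    neg <- startsWith(l, "!")
    nm <- sub("^!", "", l)
    col <- X[, nm]
    out <- out * as.integer(if (neg) 1 - col else col)
  }
  out
}

# brute-force enumeration of all supported conjunctions of <= max_len
# distinct features, skipping complement pairs and conjunctions whose
# cover equals a sub-rule's cover (extensional duplicates)
oracle_pool <- function(X, max_len, min_support) {
  n <- nrow(X)
  m <- ncol(X)
  thresh <- ceiling(min_support * n)
  keep <- !duplicated(t(X))
  X <- X[, keep, drop = FALSE]
  m <- ncol(X)
  is_comp <- function(i, j) {
    sum(X[, i] * X[, j]) == 0 && sum(X[, i]) + sum(X[, j]) == n
  }
  out <- character(0)
  for (i in seq_len(m)) {
    ci <- X[, i]
    if (sum(ci) >= thresh && sum(ci) > 0) {
      out <- c(out, colnames(X)[i])
    }
  }
  if (max_len >= 2 && m >= 2) {
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      if (is_comp(i, j)) next
      cij <- X[, i] * X[, j]
      s <- sum(cij)
      if (s >= thresh && s < sum(X[, i]) && s < sum(X[, j])) {
        out <- c(out, paste(sort(colnames(X)[c(i, j)]), collapse = "&"))
      }
    }
  }
  if (max_len >= 3 && m >= 3) {
    for (i in seq_len(m - 2)) for (j in (i + 1):(m - 1)) for (l in (j + 1):m) {
      if (is_comp(i, j) || is_comp(i, l) || is_comp(j, l)) next
      c3 <- X[, i] * X[, j] * X[, l]
      s <- sum(c3)
      sub <- c(sum(X[, i] * X[, j]), sum(X[, i] * X[, l]), sum(X[, j] * X[, l]))
      if (s >= thresh && all(s < sub)) {
        out <- c(out, paste(sort(colnames(X)[c(i, j, l)]), collapse = "&"))
      }
    }
  }
  sort(out)
}

# exhaustive argmax of the unnormalized posterior over all subsets of a pool
oracle_map <- function(pool_rules, X, y, prior, lik) {
  K <- length(pool_rules)
  best <- NULL
  best_score <- -Inf
  for (mask in 0:(2^K - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(K) - 1)) > 0)
    rules <- pool_rules[sel]
    sc <- brs_log_posterior(rules, X, y, prior, lik)
    if (sc > best_score) {
      best_score <- sc
      best <- rules
    }
  }
  list(rules = best, score = best_score)
}

# a tiny survey config used by several files
tiny_sim <- function(n = 400, seed = 1, rules = headline_rules(),
                     noise = 0, ...) {
  simulation_config(n = n, seed = seed, planted_rules = rules,
                    noise_rate = noise, ...)
}

planted_rule_strings <- function() {
  c(paste(sort(c("Selfd_high", "health_med_or_high", "workt_low")),
          collapse = "&"),
    paste(sort(c("Sleepq_med_or_high", "age_high", "workt_low")),
          collapse = "&"))
}
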