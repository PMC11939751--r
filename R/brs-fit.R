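#' Prior over rule sets
#'
#' The prior penalizes rule-set size through a Poisson distribution on the
#' number of rules and penalizes rule length through a probability vector
#' over lengths 1..`max_len`. With `lambda_rules = 3` the prior favours the
#' small (2--3 rule) solutions the method is designed to report.
#'
#' @param lambda_rules Poisson mean for the number of rules (> 0).
#' @param length_weights Probability vector over rule lengths; default
#'   uniform over 1..`max_len`.
#' @param max_len Maximum rule length.
#' @return An object of class `brs_prior`.
#' @export
brs_prior <- function(lambda_rules = 3, length_weights = NULL, max_len = 3) {
  stopifnot(lambda_rules > 0)
  if (is.null(length_weights)) length_weights <- rep(1 / max_len, max_len)
  if (abs(sum(length_weights) - 1) > 1e-8) {
    stop("length_weights must sum to 1")
  }
  structure(list(lambda_rules = lambda_rules, length_weights = length_weights),
            class = "brs_prior")
}

#' Beta-Binomial likelihood parameters
#'
#' Pseudo-counts of the Beta priors on the positive rate inside the
#' covered stratum (`alpha_pos`, `beta_pos`) and inside the uncovered
#' stratum (`alpha_neg`, `beta_neg`). The defaults encode a strong belief
#' that covered rows are positive and uncovered rows negative, which is
#' what makes low-precision rules unattractive.
#'
#' @param alpha_pos,beta_pos,alpha_neg,beta_neg Positive pseudo-counts.
#' @return An object of class `brs_likelihood`.
#' @export
brs_likelihood <- function(alpha_pos = 100, beta_pos = 1,
                           alpha_neg = 1, beta_neg = 100) {
  stopifnot(alpha_pos > 0, beta_pos > 0, alpha_neg > 0, beta_neg > 0)
  structure(list(alpha_pos = alpha_pos, beta_pos = beta_pos,
                 alpha_neg = alpha_neg, beta_neg = beta_neg),
            class = "brs_likelihood")
}

#' Chain configuration for the annealed posterior search
#'
#' @param n_chains Number of independent chains (default 10).
#' @param n_iters Iterations per chain (default 10000).
#' @param seed RNG seed.
#' @param temp_start,temp_end Geometric annealing schedule endpoints.
#' @param move_probs Probabilities of the add / remove / replace proposals.
#' @param polish If `TRUE` (default), each chain ends with a greedy
#'   hill-climb (best single add, remove or swap until no move improves
#'   the posterior), so every chain reports a local mode.
#' @return An object of class `brs_chains`.
#' @export
brs_chains <- function(n_chains = 10, n_iters = 10000, seed = 1,
                       temp_start = 1.0, temp_end = 0.01,
                       move_probs = c(add = 0.4, remove = 0.4, replace = 0.2),
                       polish = TRUE) {
  stopifnot(n_chains >= 1, n_iters >= 1, temp_start > 0, temp_end > 0)
  if (abs(sum(move_probs) - 1) > 1e-8) stop("move_probs must sum to 1")
  structure(list(n_chains = n_chains, n_iters = n_iters,
                 seed = as.integer(seed), temp_start = temp_start,
                 temp_end = temp_end, move_probs = move_probs,
                 polish = isTRUE(polish)),
            class = "brs_chains")
}

#' Predict with an OR-of-ANDs rule set
#'
#' A row is predicted positive when any rule in the set covers it; the
#' empty rule set predicts all zeros.
#'
#' @param rules A list of rules (character literal vectors or `"a&b"`
#'   strings), or a `brs_fit` object (its MAP rule set is used).
#' @param features A `binary_features` object or 0/1 matrix.
#' @return Integer 0/1 predictions.
#' @export
brs_predict <- function(rules, features) {
  if (inherits(rules, "brs_fit")) rules <- rules$map_rules
  X <- feature_matrix(features)
  if (length(rules) == 0) return(integer(nrow(X)))
  covered <- rep(0L, nrow(X))
  for (r in rules) covered <- covered | rule_cover(r, X)
  as.integer(covered)
}

#' Log prior density of a rule set
#'
#' `log Poisson(|A|; lambda) + sum over rules of log length_weight[len]`;
#' strictly decreasing in `|A|` once `|A| >= lambda_rules`.
#'
#' @param rules List of rules (literal vectors or strings).
#' @param prior A [brs_prior()].
#' @return Log prior (unnormalized over rule composition).
#' @export
brs_log_prior <- function(rules, prior = brs_prior()) {
  lens <- vapply(rules, function(r) length(parse_rule(r)), integer(1))
  if (any(lens > length(prior$length_weights))) return(-Inf)
  stats::dpois(length(rules), prior$lambda_rules, log = TRUE) +
    sum(log(prior$length_weights[lens]))
}

# likelihood from the confusion counts of a prediction; both strata place
# the Beta prior on their positive rate, so the defaults (100,1) / (1,100)
# expect covered rows positive and uncovered rows negative
loglik_counts <- function(tp, fp, tn, fn, lik) {
  lbeta(tp + lik$alpha_pos, fp + lik$beta_pos) -
    lbeta(lik$alpha_pos, lik$beta_pos) +
    lbeta(fn + lik$alpha_neg, tn + lik$beta_neg) -
    lbeta(lik$alpha_neg, lik$beta_neg)
}

#' Log marginal likelihood of the data given a rule set
#'
#' Beta-Binomial marginal over the covered stratum (true/false positives)
#' and the uncovered stratum (false negatives/true negatives), with the
#' Beta prior on each stratum's positive rate:
#' `log B(TP + a_pos, FP + b_pos) - log B(a_pos, b_pos) +
#'  log B(FN + a_neg, TN + b_neg) - log B(a_neg, b_neg)`.
#'
#' @param rules List of rules.
#' @param features A `binary_features` object or 0/1 matrix.
#' @param labels 0/1 labels.
#' @param lik A [brs_likelihood()].
#' @return Log likelihood.
#' @export
brs_log_likelihood <- function(rules, features, labels = NULL,
                               lik = brs_likelihood()) {
  if (is.null(labels) && inherits(features, "binary_features")) {
    labels <- features$y
  }
  if (!all(labels %in% c(0, 1))) stop("labels must be binary 0/1")
  pred <- brs_predict(rules, features)
  tp <- sum(pred == 1 & labels == 1); fp <- sum(pred == 1 & labels == 0)
  tn <- sum(pred == 0 & labels == 0); fn <- sum(pred == 0 & labels == 1)
  loglik_counts(tp, fp, tn, fn, lik)
}

#' Unnormalized log posterior of a rule set
#'
#' @inheritParams brs_log_likelihood
#' @param prior A [brs_prior()].
#' @return `brs_log_prior(rules) + brs_log_likelihood(rules, ...)`.
#' @export
brs_log_posterior <- function(rules, features, labels = NULL,
                              prior = brs_prior(), lik = brs_likelihood()) {
  brs_log_prior(rules, prior) +
    brs_log_likelihood(rules, features, labels, lik)
}

# cover matrix (n x K logical) of a pool
pool_cover_matrix <- function(pool, X) {
  K <- nrow(pool)
  C <- matrix(FALSE, nrow(X), K)
  for (k in seq_len(K)) C[, k] <- rule_cover(pool$rule[k], X) == 1L
  C
}

#' Fit a Bayesian rule set by annealed multi-chain search
#'
#' Each chain runs a Metropolis search over subsets of the candidate pool
#' with add / remove / replace moves under a geometrically decaying
#' temperature; the best-scoring rule set across all chains is returned as
#' the MAP estimate. Add and replace proposals are guided: a currently
#' uncovered positive row is sampled and the new rule is drawn from the
#' pool rules covering it (falling back to a uniform pool draw), which lets
#' the search reach high-precision rules inside pools of thousands of
#' candidates.
#'
#' @param features A `binary_features` object or 0/1 matrix.
#' @param labels 0/1 labels.
#' @param pool A `rule_pool` from [mine_candidates()].
#' @param prior A [brs_prior()].
#' @param lik A [brs_likelihood()].
#' @param chains A [brs_chains()].
#' @return An object of class `brs_fit`: `map_rules` (list of literal
#'   vectors), `map_score`, `chain_best` scores, `acceptance_rates`,
#'   `seed`, and the config echo.
#' @export
brs_fit <- function(features, labels = NULL, pool,
                    prior = brs_prior(), lik = brs_likelihood(),
                    chains = brs_chains()) {
  X <- feature_matrix(features)
  if (is.null(labels) && inherits(features, "binary_features")) {
    labels <- features$y
  }
  if (!nrow(pool)) stop("candidate pool is empty; lower min_support or add features")
  y <- as.integer(labels == 1)
  n <- nrow(X)
  C <- pool_cover_matrix(pool, X)
  K <- ncol(C)
  lens <- pool$length
  pos_rows <- which(y == 1)
  npos <- length(pos_rows)

  score_counts <- function(nsel, len_logw, tp, fp) {
    stats::dpois(nsel, prior$lambda_rules, log = TRUE) + len_logw +
      loglik_counts(tp, fp, n - npos - fp, npos - tp, lik)
  }
  logw <- log(prior$length_weights)[lens]
  score_state <- function(sel, covcount) {
    pred <- covcount > 0L
    tp <- sum(y[pred]); fp <- sum(pred) - tp
    score_counts(length(sel), sum(logw[sel]), tp, fp)
  }

  # greedy hill-climb to the nearest local mode: best single add, remove or
  # one-for-one swap, repeated until no move improves the score
  polish_state <- function(sel, covcount, score) {
    Cy <- C & (y == 1L)
    repeat {
      pred <- covcount > 0L
      tp <- sum(y[pred]); fp <- sum(pred) - tp
      uncov <- covcount == 0L
      best_gain <- 0; best <- NULL
      # adds: new coverage gained from uncovered rows
      a1 <- colSums(Cy[uncov, , drop = FALSE])
      a0 <- colSums(C[uncov, , drop = FALSE]) - a1
      add_scores <- score_counts(length(sel) + 1L, sum(logw[sel]) + logw,
                                 tp + a1, fp + a0)
      add_scores[sel] <- -Inf
      k <- which.max(add_scores)
      if (length(k) && add_scores[k] - score > best_gain) {
        best_gain <- add_scores[k] - score
        best <- list(op = "add", k = k)
      }
      for (r in sel) {
        solo <- covcount == 1L & C[, r]        # rows only this rule covers
        dtp <- sum(y[solo]); dfp <- sum(solo) - dtp
        rm_score <- score_counts(length(sel) - 1L, sum(logw[sel]) - logw[r],
                                 tp - dtp, fp - dfp)
        if (rm_score - score > best_gain) {
          best_gain <- rm_score - score
          best <- list(op = "remove", r = r)
        }
        # swaps: remove r, then the best add on the reduced state
        uncov_r <- uncov | solo
        s1 <- colSums(Cy[uncov_r, , drop = FALSE])
        s0 <- colSums(C[uncov_r, , drop = FALSE]) - s1
        sw_scores <- score_counts(length(sel), sum(logw[sel]) - logw[r] + logw,
                                  tp - dtp + s1, fp - dfp + s0)
        sw_scores[sel] <- -Inf
        k <- which.max(sw_scores)
        if (length(k) && sw_scores[k] - score > best_gain) {
          best_gain <- sw_scores[k] - score
          best <- list(op = "swap", r = r, k = k)
        }
      }
      if (is.null(best)) break
      if (best$op == "add") {
        sel <- c(sel, best$k); covcount <- covcount + C[, best$k]
      } else if (best$op == "remove") {
        sel <- setdiff(sel, best$r); covcount <- covcount - C[, best$r]
      } else {
        sel <- c(setdiff(sel, best$r), best$k)
        covcount <- covcount - C[, best$r] + C[, best$k]
      }
      score <- score + best_gain
    }
    list(sel = sel, covcount = covcount, score = score)
  }

  set.seed(chains$seed)
  temps <- chains$temp_start *
    (chains$temp_end / chains$temp_start)^
      (if (chains$n_iters > 1) (seq_len(chains$n_iters) - 1) / (chains$n_iters - 1) else 0)

  best_score <- -Inf
  best_sel <- integer(0)
  chain_best <- numeric(chains$n_chains)
  acc_rates <- numeric(chains$n_chains)

  propose_add <- function(sel, covcount) {
    cand <- setdiff(seq_len(K), sel)
    if (!length(cand)) return(NA_integer_)
    fn_rows <- pos_rows[covcount[pos_rows] == 0L]
    if (length(fn_rows)) {
      row <- fn_rows[sample.int(length(fn_rows), 1)]
      guided <- cand[C[row, cand]]
      if (length(guided)) return(guided[sample.int(length(guided), 1)])
    }
    cand[sample.int(length(cand), 1)]
  }

  for (ch in seq_len(chains$n_chains)) {
    sel <- integer(0)
    covcount <- integer(n)
    score <- score_state(sel, covcount)
    if (score > best_score) { best_score <- score; best_sel <- sel }
    cbest <- score
    accepted <- 0L
    for (it in seq_len(chains$n_iters)) {
      move <- sample.int(3, 1, prob = chains$move_probs)
      new_sel <- sel
      new_cov <- covcount
      if (move == 1L || (move == 2L && !length(sel)) ) {        # add
        k <- propose_add(sel, covcount)
        if (is.na(k)) next
        new_sel <- c(sel, k)
        new_cov <- covcount + C[, k]
      } else if (move == 2L) {                                  # remove
        d <- sel[sample.int(length(sel), 1)]
        new_sel <- setdiff(sel, d)
        new_cov <- covcount - C[, d]
      } else {                                                  # replace
        if (!length(sel)) next
        d <- sel[sample.int(length(sel), 1)]
        mid_sel <- setdiff(sel, d)
        mid_cov <- covcount - C[, d]
        k <- propose_add(mid_sel, mid_cov)
        if (is.na(k)) next
        new_sel <- c(mid_sel, k)
        new_cov <- mid_cov + C[, k]
      }
      new_score <- score_state(new_sel, new_cov)
      if (log(stats::runif(1)) < (new_score - score) / temps[it]) {
        sel <- new_sel; covcount <- new_cov; score <- new_score
        accepted <- accepted + 1L
        if (score > cbest) cbest <- score
        if (score > best_score) { best_score <- score; best_sel <- sel }
      }
    }
    if (chains$polish) {
      pol <- polish_state(sel, covcount, score)
      if (pol$score > cbest) cbest <- pol$score
      if (pol$score > best_score) {
        best_score <- pol$score; best_sel <- pol$sel
      }
    }
    chain_best[ch] <- cbest
    acc_rates[ch] <- accepted / chains$n_iters
  }

  map_rules <- lapply(pool$rule[sort(best_sel)], parse_rule)
  structure(list(map_rules = map_rules,
                 map_rule_strings = vapply(map_rules, rule_string, character(1)),
                 map_score = best_score, chain_best = chain_best,
                 acceptance_rates = acc_rates, seed = chains$seed,
                 prior = prior, likelihood = lik, chains = chains),
            class = "brs_fit")
}

#' Serialize a fit as JSON
#'
#' @param fit A `brs_fit`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_brs_fit <- function(fit, path) {
  jsonlite::write_json(
    list(map_rules = lapply(fit$map_rules, as.list),
         map_score = fit$map_score, chain_best = fit$chain_best,
         acceptance_rates = fit$acceptance_rates, seed = fit$seed),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
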