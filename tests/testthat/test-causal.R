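test_that("treatment assignment cuts at mean plus one SD", {
  expect_equal(assign_treatment(c(1, 2, 2, 3, 5)), c(0L, 0L, 0L, 0L, 1L))
  v <- c(1, 2, 2, 3, 5)
  expect_equal(assign_treatment(v * 3 + 10), assign_treatment(v))
  expect_error(assign_treatment(rep(2, 10)), "degenerate")
})

test_that("intercept-only propensity scores equal the treated fraction", {
  t <- c(rep(1, 3), rep(0, 7))
  m <- estimate_propensity(data.frame(row.names = seq_along(t)), t)
  expect_equal(m$scores, rep(0.3, 10), tolerance = 1e-6)
})

test_that("logistic propensity recovers simulated coefficients", {
  set.seed(301)
  n <- 5000
  W <- data.frame(w = rnorm(n))
  eta <- 0.5 - 1.0 * W$w
  t <- rbinom(n, 1, plogis(eta))
  m <- estimate_propensity(W, t)
  expect_lt(abs(m$coefficients[["(Intercept)"]] - 0.5), 0.1)
  expect_lt(abs(m$coefficients[["w"]] + 1.0), 0.1)
  # scores are invariant to affine rescaling of a covariate
  m2 <- estimate_propensity(data.frame(w = 10 * W$w + 3), t)
  expect_equal(m$scores, m2$scores, tolerance = 1e-6)
})

test_that("perfect separation is reported with the offending covariate", {
  n <- 60
  W <- data.frame(sep = c(rep(0, 30), rep(1, 30)), noise = rnorm(n))
  t <- W$sep
  expect_error(estimate_propensity(W, t), "separation")
})

test_that("nearest-neighbour matching follows the greedy order and tie rules", {
  scores <- c(0.8, 0.5, 0.75, 0.3, 0.6, 0.55)
  treat <- c(1, 0, 0, 0, 1, 0)
  m <- match_propensity(scores, treat, "nearest")
  # treated 1 (0.8) first: closest control is 3 (0.75); then treated 5
  # (0.6): closest remaining is 6 (0.55)
  expect_equal(m$pairs$treated, c(1L, 5L))
  expect_equal(m$pairs$control, c(3L, 6L))
  # brute-force check of the greedy assignment on the same fixture
  expect_equal(m$pairs$distance, c(0.05, 0.05), tolerance = 1e-12)
  # matching without replacement: control indices are disjoint
  expect_false(anyDuplicated(m$pairs$control) > 0)
  # simple two-control case: 0.8 pairs with 0.75, not 0.5
  m2 <- match_propensity(c(0.8, 0.5, 0.75), c(1, 0, 0), "nearest")
  expect_equal(m2$pairs$control, 3L)
  # a zero caliper forms no pairs without exact ties
  expect_warning(m3 <- match_propensity(scores, treat, "caliper", caliper = 0),
                 "caliper")
  expect_equal(nrow(m3$pairs), 0)
  # radius matching returns every control within the band, with replacement
  m4 <- match_propensity(scores, treat, "radius", caliper = 0.21)
  expect_setequal(m4$pairs$control[m4$pairs$treated == 1], 3L)
  expect_setequal(m4$pairs$control[m4$pairs$treated == 5], c(2L, 3L, 6L))
})

test_that("inverse probability weights take their closed form", {
  w <- ipw_weights(c(0.5, 0.2), c(1, 0))
  expect_equal(w$weights, c(2.0, 1.25))
  scores <- runif(50, 0.1, 0.9)
  treat <- rbinom(50, 1, scores)
  treat[1] <- 1; treat[2] <- 0
  w2 <- ipw_weights(scores, treat)$weights
  expect_equal(w2[treat == 1] * scores[treat == 1],
               rep(1, sum(treat == 1)))
  expect_equal(w2[treat == 0] * (1 - scores[treat == 0]),
               rep(1, sum(treat == 0)))
  expect_error(ipw_weights(c(0, 0.5), c(1, 0)), "strictly inside")
})

test_that("IPW balances covariates on a confounded design", {
  set.seed(311)
  n <- 5000
  w <- rnorm(n)
  t <- rbinom(n, 1, plogis(0.3 + 0.8 * w))
  p <- estimate_propensity(data.frame(w = w), t)$scores
  wt <- ipw_weights(p, t)$weights
  raw_gap <- abs(mean(w[t == 1]) - mean(w[t == 0]))
  bal_gap <- abs(weighted.mean(w[t == 1], wt[t == 1]) -
                 weighted.mean(w[t == 0], wt[t == 0]))
  expect_gt(raw_gap, 0.3)
  expect_lt(bal_gap, 0.1)
})

test_that("mediation recovers planted direct and indirect effects", {
  set.seed(321)
  n <- 2000
  rule <- rbinom(n, 1, 0.3)
  z <- rnorm(n)
  m <- 0.5 + 0.5 * rule + 0.3 * z + rnorm(n)
  y <- 0.2 + 0.8 * m + 0.3 * rule + 0.2 * z + rnorm(n)
  d <- data.frame(y = y, m = m, z = z, rule1 = rule)
  spec <- mediation_spec("y", "m", controls = "z", rules = "rule1")
  fit <- mediation_fit(d, spec)
  eff <- fit$effects
  expect_lt(abs(eff$indirect - 0.4), 2 * eff$indirect_se)
  expect_lt(abs(eff$direct - 0.3), 2 * eff$direct_se)
  # total effect decomposes into direct + indirect on the linear system
  total <- coef(lm(y ~ rule1 + z, d))[["rule1"]]
  expect_lt(abs(total - (eff$indirect + eff$direct)), 0.1)
})

test_that("null effects are recovered as null", {
  set.seed(331)
  n <- 1500
  rule <- rbinom(n, 1, 0.4)
  m <- rnorm(n)
  y <- 0.5 * m + rnorm(n)
  d <- data.frame(y = y, m = m, rule1 = rule)
  fit <- mediation_fit(d, mediation_spec("y", "m", rules = "rule1"))
  expect_lt(abs(fit$effects$indirect), 2 * fit$effects$indirect_se + 1e-8)
  expect_lt(abs(fit$effects$direct), 2 * fit$effects$direct_se)
})

test_that("duplicated rule indicators are rejected by name", {
  set.seed(341)
  n <- 200
  r <- rbinom(n, 1, 0.5)
  d <- data.frame(y = rnorm(n), m = rnorm(n), rule1 = r, rule2 = r)
  expect_error(
    mediation_fit(d, mediation_spec("y", "m", rules = c("rule1", "rule2"))),
    "rule2")
  expect_error(mediation_spec("y", "y", rules = "r"), "two roles")
})

test_that("grouped specs include the treatment term, ungrouped omit it", {
  set.seed(351)
  n <- 500
  d <- data.frame(tr = rbinom(n, 1, 0.5), m = rnorm(n), y = rnorm(n),
                  rule1 = rbinom(n, 1, 0.3))
  g <- mediation_fit(d, mediation_spec("y", "m", treatment = "tr",
                                       rules = "rule1"))
  expect_true("tr" %in% g$eq_mediator$term)
  u <- mediation_fit(d, mediation_spec("y", "m", rules = "rule1"))
  expect_false("tr" %in% u$eq_mediator$term)
})

test_that("the LASSO filter keeps signal and discards noise indicators", {
  set.seed(361)
  n <- 1000
  sig <- rbinom(n, 1, 0.4)
  y <- 1.5 * sig + rnorm(n)
  keep <- filter_rules_lasso(cbind(sig = sig), y, seed = 1)
  expect_equal(keep, 1L)

  none_kept <- 0
  for (s in 1:20) {
    noise <- matrix(rbinom(n * 20, 1, 0.3), n, 20)
    yn <- rnorm(n)
    kept <- suppressWarnings(filter_rules_lasso(noise, yn, seed = s))
    if (length(kept) == 0) none_kept <- none_kept + 1
  }
  expect_gte(none_kept, 18)

  # duplicated indicators: at most one of the pair survives
  dup <- cbind(a = sig, b = sig,
               c = rbinom(n, 1, 0.5))
  kept <- suppressWarnings(filter_rules_lasso(dup, y, seed = 2))
  expect_lte(sum(kept %in% c(1, 2)), 1)
})
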