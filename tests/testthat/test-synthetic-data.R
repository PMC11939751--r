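test_that("same config and seed give identical tables", {
  cfg <- tiny_sim(n = 300, seed = 11, noise = 0.1)
  a <- generate_survey(cfg)
  b <- generate_survey(cfg)
  expect_identical(plain_df(a), plain_df(b))
  expect_identical(attr(a, "generator")$labels, attr(b, "generator")$labels)
})

test_that("noiseless generation ties the high outcome exactly to rule satisfaction", {
  cfg <- tiny_sim(n = 500, seed = 7, noise = 0)
  tab <- generate_survey(cfg)
  gen <- attr(tab, "generator")
  # top original coding of the reverse-coded outcome is 1 (reversed 5)
  high <- tab$Jobs == 1
  expect_identical(unname(high), unname(gen$covered))
  expect_identical(unname(gen$labels == 1), unname(gen$covered))
})

test_that("target support is reached within binomial error", {
  rule <- planted_rule(list(list(variable = "health", category = "med_or_high"),
                            list(variable = "workt", category = "low")),
                       target_support = 0.2)
  cfg <- simulation_config(n = 5000, seed = 3, planted_rules = list(rule),
                           noise_rate = 0)
  tab <- generate_survey(cfg)
  emp <- mean(attr(tab, "generator")$covered)
  tol <- 3 * sqrt(0.2 * 0.8 / 5000)
  expect_lt(abs(emp - 0.2), tol)
})

test_that("infeasible planted rules fail with an explicit message", {
  r1 <- planted_rule(list(list(variable = "gender", category = "1")),
                     target_support = 0.6)
  r2 <- planted_rule(list(list(variable = "marry", category = "1")),
                     target_support = 0.5)
  cfg <- simulation_config(n = 100, seed = 1, planted_rules = list(r1, r2),
                           noise_rate = 0)
  expect_error(generate_survey(cfg), "infeasible")
  expect_error(
    simulation_config(n = 100, seed = 1, noise_rate = 0,
                      planted_rules = list(planted_rule(list(
                        list(variable = "nosuch", category = "low"))))),
    "undeclared")
})

test_that("outcome base rate without planted rules matches the noise rate", {
  cfg <- simulation_config(n = 4000, seed = 5, planted_rules = list(),
                           noise_rate = 0.15)
  tab <- generate_survey(cfg)
  rate <- mean(attr(tab, "generator")$labels)
  expect_lt(abs(rate - 0.15), 3 * sqrt(0.15 * 0.85 / 4000))
})

test_that("all draws respect the declared level sets and ranges", {
  cfg <- tiny_sim(n = 600, seed = 2, noise = 0.1)
  tab <- generate_survey(cfg)
  for (s in attr(tab, "specs")) {
    v <- tab[[s$name]]
    if (s$kind == "ordinal") {
      expect_true(all(v %in% seq_len(s$levels)), label = s$name)
    } else if (s$kind == "binary") {
      expect_true(all(v %in% c(0, 1)), label = s$name)
    } else {
      expect_true(all(v >= s$range[1] & v <= s$range[2]), label = s$name)
    }
  }
})

test_that("missingness injection hits its per-variable rates", {
  cfg <- tiny_sim(n = 2000, seed = 9)
  tab <- generate_survey(cfg)
  out <- inject_missingness(tab, c(income = 0.15), seed = 4)
  expect_lt(abs(mean(is.na(out$income)) - 0.15), 0.03)
  same <- inject_missingness(tab, c(income = 0), seed = 4)
  expect_identical(plain_df(same), plain_df(tab))
  all_gone <- inject_missingness(tab, c(income = 1), seed = 4)
  expect_true(all(is.na(all_gone$income)))
  expect_error(inject_missingness(tab, c(bogus = 0.1), seed = 1), "unknown")
})

test_that("outlier injection contaminates roughly rate x n rows above 84 h", {
  cfg <- tiny_sim(n = 1000, seed = 13)
  tab <- generate_survey(cfg)
  out <- inject_outliers(tab, 0.05, seed = 8)
  n_out <- sum(out$workt > 84)
  expect_gt(n_out, 50 - 3 * sqrt(1000 * 0.05 * 0.95))
  expect_lt(n_out, 50 + 3 * sqrt(1000 * 0.05 * 0.95))
  expect_identical(plain_df(inject_outliers(tab, 0, seed = 8))$workt,
                   plain_df(tab)$workt)
  # the preparation filter removes exactly the injected rows
  cleaned <- remove_outliers(out)
  expect_equal(nrow(cleaned), nrow(out) - n_out)
  expect_error(inject_outliers(tab, 1.5, seed = 1), "rate")
})

test_that("mining recovers every planted rule whose support clears the threshold", {
  cfg <- tiny_sim(n = 800, seed = 21, noise = 0)
  tab <- generate_survey(cfg)
  bf <- prepare_survey(tab)
  pool <- mine_candidates(bf)
  for (ps in planted_rule_strings()) {
    planted_cov <- mean(rule_cover(ps, bf$X))
    if (planted_cov >= 0.05) {
      expect_true(ps %in% pool$rule, label = ps)
    }
  }
})

test_that("survey tables round-trip through CSV with a JSON sidecar", {
  cfg <- tiny_sim(n = 50, seed = 31)
  tab <- generate_survey(cfg)
  csv <- tempfile(fileext = ".csv")
  write_survey(tab, csv)
  side <- jsonlite::read_json(sub("csv$", "json", csv))
  expect_equal(side$seed, 31)
  expect_length(side$planted_rules, 2)
  back <- read_survey(csv)
  expect_equal(plain_df(back), plain_df(tab), tolerance = 1e-12)
})
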