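test_that("coverage decomposition equals brute-force tallies", {
  X <- random_binary_matrix(100, 6, seed = 201)
  y <- random_labels(100, 202)
  rule <- c("f1", "f4")
  cf <- coverage_decomposition(rule, X, y)
  cov <- oracle_cover(rule, X)
  expect_equal(cf$tp, sum(cov == 1 & y == 1))
  expect_equal(cf$fp, sum(cov == 1 & y == 0))
  # labels all positive: no rule can produce false positives
  cf1 <- coverage_decomposition(rule, X, rep(1, 100))
  expect_equal(cf1$fp, 0)
  # a rule covering nothing
  X0 <- cbind(X, never = 0L)
  expect_equal(coverage_decomposition("never", X0, y), list(tp = 0L, fp = 0L))
})

test_that("classification outcome labels match the confusion matrix", {
  X <- random_binary_matrix(100, 5, seed = 203)
  y <- random_labels(100, 204)
  rules <- list(c("f1", "f2"), "f4")
  lab <- classification_outcomes(rules, X, y)
  pred <- brs_predict(rules, X)
  expect_equal(sum(table(lab)), 100)
  expect_equal(unname(table(lab)["TP"]), sum(pred == 1 & y == 1))
  expect_equal(unname(table(lab)["FP"]), sum(pred == 1 & y == 0))
  expect_equal(unname(table(lab)["FN"]), sum(pred == 0 & y == 1))
  expect_equal(unname(table(lab)["TN"]), sum(pred == 0 & y == 0))
  # empty rule set: TN where truth 0, FN where truth 1
  lab0 <- classification_outcomes(list(), X, y)
  expect_true(all(lab0[y == 1] == "FN") && all(lab0[y == 0] == "TN"))
  # a perfect rule set yields only TP/TN
  labp <- classification_outcomes(list("f1"), X, X[, "f1"])
  expect_true(all(labp %in% c("TP", "TN")))
})

test_that("interaction edges match brute-force pair counting", {
  rules <- list(c("age_high", "workt_low", "Sleepq_med_or_high"),
                c("age_high", "workt_low", "health_high"),
                "Selfd_high")
  edges <- interaction_edges(rules)
  # one 3-literal rule alone contributes its three pairs with weight 1
  single <- interaction_edges(rules[1])
  expect_equal(nrow(single), 3)
  expect_true(all(single$weight == 1))
  # shared pair across the first two rules accumulates weight 2
  w <- edges$weight[edges$var1 == "age" & edges$var2 == "workt"]
  expect_equal(w, 2)
  # brute-force recount
  pair_count <- new.env()
  for (r in rules) {
    vars <- sort(unique(sub("_(low_or_med|med_or_high|low|high|1)$", "", r)))
    if (length(vars) < 2) next
    for (cmb in utils::combn(vars, 2, simplify = FALSE)) {
      key <- paste(cmb, collapse = "|")
      assign(key, (if (exists(key, pair_count)) get(key, pair_count) else 0) + 1,
             pair_count)
    }
  }
  for (i in seq_len(nrow(edges))) {
    expect_equal(edges$weight[i],
                 get(paste(c(edges$var1[i], edges$var2[i]), collapse = "|"),
                     pair_count))
  }
  # disjoint rules share no edges
  expect_equal(nrow(interaction_edges(list(c("a_low", "b_low"),
                                           c("c_low", "d_low")))), 2)
  expect_equal(interaction_edges(list(c("a_low", "b_low"),
                                      c("c_low", "d_low")))$weight, c(1, 1))
})

test_that("bootstrap stability gives planted rules prevalence 1 on noiseless data", {
  # n large enough that every resample keeps rows distinguishing each
  # planted rule from its sub-rules (the rules share the work-time literal)
  cfg <- tiny_sim(n = 800, seed = 211, noise = 0)
  tab <- generate_survey(cfg)
  bf <- prepare_survey(tab)
  rep <- bootstrap_stability(bf$X, bf$y,
                             fit_config = brs_chains(n_chains = 2,
                                                     n_iters = 300),
                             B = 12, seed = 212)
  prev <- setNames(rep$rules$prevalence, rep$rules$rule)
  for (ps in planted_rule_strings()) {
    expect_equal(unname(prev[ps]), 1.0, label = ps)
  }
  # aggregation keeps exactly the rules at or above the threshold
  expect_setequal(vapply(rep$aggregated, function(r)
    paste(sort(r), collapse = "&"), character(1)),
    rep$rules$rule[rep$rules$prevalence >= rep$prevalence_threshold])
  # a rule absent from every MAP set has no record at all
  expect_false("age_low&health_low" %in% rep$rules$rule)
  # percentile CIs bracket the mean signed coverage
  signed <- rep$rules$tp_coverage + rep$rules$fp_coverage
  expect_true(mean(signed >= rep$rules$ci_low - 1e-9 &
                   signed <= rep$rules$ci_high + 1e-9) >= 0.9)
})

test_that("stability reports serialize to TSV and JSON", {
  cfg <- tiny_sim(n = 300, seed = 221, noise = 0)
  tab <- generate_survey(cfg)
  bf <- prepare_survey(tab)
  rep <- bootstrap_stability(bf$X, bf$y,
                             fit_config = brs_chains(n_chains = 2,
                                                     n_iters = 200),
                             B = 5, seed = 222)
  tsv <- tempfile(fileext = ".tsv")
  write_stability_report(rep, tsv)
  back <- read.delim(tsv)
  expect_equal(back$rule, rep$rules$rule)
  meta <- jsonlite::read_json(sub("tsv$", "json", tsv))
  expect_equal(meta$B, 5)
})
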