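#!/usr/bin/env Rscript
# Candidate mining (conjunctions of <= 3 literals, >= 5% support, capped
# at 5000 by information gain) and the Bayesian rule set fit: Poisson
# prior on the number of rules, Beta-Binomial classification likelihood,
# annealed multi-chain search with greedy polish.

library(brsurvey)

d <- utils::read.csv("results/binary_matrix.csv")
y <- d$outcome
X <- as.matrix(d[setdiff(names(d), "outcome")])

pool <- mine_candidates(X, y, mining_config(max_len = 3, min_support = 0.05,
                                            max_rules = 5000))
write_rule_pool(pool, "results/rule_pool.tsv")
cat("candidate pool:", nrow(pool), "rules\n")

fit <- brs_fit(X, y, pool,
               prior = brs_prior(), lik = brs_likelihood(),
               chains = brs_chains(n_chains = 10, n_iters = 2000, seed = 7))
write_brs_fit(fit, "results/fit.json")

cat("MAP rule set (log posterior ", round(fit$map_score, 2), "):\n", sep = "")
for (r in fit$map_rules) cat("  IF", paste(r, collapse = " AND "), "\n")
pred <- brs_predict(fit, X)
cat("training accuracy:", round(mean(pred == y), 3), "\n")
cat("confusion:", paste(names(table(classification_outcomes(fit$map_rules, X, y))),
                        table(classification_outcomes(fit$map_rules, X, y)),
                        collapse = ", "), "\n")
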