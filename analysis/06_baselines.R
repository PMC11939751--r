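#!/usr/bin/env Rscript
# Comparison methods on the same binary matrix: LASSO over up-to-3rd-order
# interactions with an OLS refit, decision-tree rule extraction at a
# complexity matched to the aggregated rule set, and random-forest
# impurity importance. The interaction screen runs on the canonical
# (content-deduplicated) feature columns to keep the design tractable.

library(brsurvey)

d <- utils::read.csv("results/binary_matrix.csv")
y <- d$outcome
X <- as.matrix(d[setdiff(names(d), "outcome")])
Xc <- X[, !duplicated(t(X))]
cat("canonical features:", ncol(Xc), "of", ncol(X), "\n")

scr <- lasso_interaction_screen(Xc, y, max_order = 2, seed = 11)
utils::write.table(scr$terms, "results/lasso_terms.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("LASSO screen:", scr$n_design_columns, "design columns;",
    sum(scr$terms$significant), "terms significant at 5%\n")
print(utils::head(scr$terms, 8), row.names = FALSE)

tr <- tree_to_rules(Xc, y, maxdepth = 3)
cat("decision-tree rule set:\n")
for (r in tr$rules) cat("  IF", paste(r, collapse = " AND "), "\n")
acc_tree <- mean(brs_predict(tr$rules, Xc) == y)
cat("tree rule-set training accuracy:", round(acc_tree, 3), "\n")

imp <- forest_importance(Xc, y, seed = 12, ntree = 500)
utils::write.table(imp, "results/forest_importance.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("top random-forest features:\n")
print(utils::head(imp, 8), row.names = FALSE)
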