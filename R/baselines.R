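#' Interaction design matrix of binary features
#'
#' Columns are products of 1 to `max_order` distinct binary features, named
#' `a x b x c`. Combinations multiplying a feature by its column-wise
#' complement are skipped (their product is identically zero), as are
#' combinations that never fire.
#'
#' @param features A `binary_features` object or 0/1 matrix.
#' @param max_order Highest interaction order (default 3).
#' @param max_cells Memory budget: the design may not exceed this many
#'   cells (default 2e8); exceeding it fails with advice to lower the
#'   order.
#' @return Numeric matrix with named columns.
#' @export
interaction_design <- function(features, max_order = 3, max_cells = 2e8) {
  X <- feature_matrix(features)
  storage.mode(X) <- "double"
  m <- ncol(X); n <- nrow(X)
  n_terms <- sum(choose(m, seq_len(max_order)))
  if (n_terms * n > max_cells) {
    stop("interaction design would need ", format(n_terms * n, big.mark = ","),
         " cells; reduce max_order or the feature set")
  }
  s1 <- colSums(X)
  comp <- (crossprod(X) == 0) & (outer(s1, s1, `+`) == n)
  cols <- list()
  combos <- list()
  for (ord in seq_len(max_order)) {
    idx <- utils::combn(m, ord)
    for (j in seq_len(ncol(idx))) {
      ix <- idx[, j]
      if (ord > 1 && any(comp[ix, ix])) next
      v <- X[, ix[1]]
      for (k in ix[-1]) v <- v * X[, k]
      if (!any(v == 1)) next
      cols[[length(cols) + 1]] <- v
      combos[[length(combos) + 1]] <- paste(colnames(X)[ix], collapse = " x ")
    }
  }
  D <- do.call(cbind, cols)
  colnames(D) <- unlist(combos)
  D
}

#' LASSO interaction screen with OLS refit
#'
#' Builds the up-to-third-order interaction design, runs an L1 fit with a
#' cross-validated penalty, refits ordinary least squares on the non-zero
#' support, and flags terms significant at the 5% level (plain t-tests,
#' no multiplicity correction).
#'
#' @param features A `binary_features` object or 0/1 matrix.
#' @param outcome Numeric or 0/1 outcome.
#' @param max_order Highest interaction order (default 3).
#' @param seed RNG seed for the CV folds.
#' @param nfolds Number of CV folds.
#' @param max_cells Design memory budget, see [interaction_design()].
#' @return An object of class `lasso_screen`: data.frame `terms` (term,
#'   coefficient, se, p, significant) for the refit support, plus the
#'   number of design columns.
#' @export
lasso_interaction_screen <- function(features, outcome, max_order = 3,
                                     seed = 1, nfolds = 10, max_cells = 2e8) {
  D <- interaction_design(features, max_order, max_cells)
  set.seed(seed)
  foldid <- sample(rep(seq_len(nfolds), length.out = nrow(D)))
  cv <- glmnet::cv.glmnet(D, outcome, family = "gaussian", foldid = foldid)
  cf <- as.matrix(stats::coef(cv, s = "lambda.1se"))[-1, 1]
  support <- names(cf)[cf != 0]
  if (!length(support)) {
    return(structure(list(terms = data.frame(term = character(0),
                                             estimate = numeric(0),
                                             se = numeric(0), p = numeric(0),
                                             significant = logical(0)),
                          n_design_columns = ncol(D)),
                     class = "lasso_screen"))
  }
  df <- data.frame(..y = outcome, D[, support, drop = FALSE],
                   check.names = FALSE)
  ols <- stats::lm(..y ~ ., data = df)
  s <- summary(ols)$coefficients
  s <- s[rownames(s) != "(Intercept)", , drop = FALSE]
  terms <- data.frame(term = gsub("^`|`$", "", rownames(s)),
                      estimate = s[, 1], se = s[, 2], p = s[, 4],
                      significant = s[, 4] < 0.05,
                      row.names = NULL, stringsAsFactors = FALSE)
  structure(list(terms = terms[order(terms$p), , drop = FALSE],
                 n_design_columns = ncol(D)),
            class = "lasso_screen")
}

#' Extract a rule set from a classification tree
#'
#' Fits a CART tree and reads the conjunction along each path to a leaf
#' predicted positive as one rule; their union is the rule set. Splits
#' going left on a binary feature (value < 0.5) become negated literals
#' (`"!feature"`).
#'
#' @param features A `binary_features` object or 0/1 matrix.
#' @param outcome 0/1 outcome.
#' @param maxdepth Maximum tree depth (chosen to keep the rule set
#'   comparable to the aggregated rule-set solution in number and length
#'   of rules).
#' @param cp rpart complexity parameter.
#' @param minbucket Minimum leaf size.
#' @return An object of class `tree_rules`: list of rules (character
#'   literal vectors), the fitted `rpart` object, and a warning flag for
#'   degenerate single-leaf trees.
#' @export
tree_to_rules <- function(features, outcome, maxdepth = 3, cp = 0.01,
                          minbucket = 7) {
  X <- feature_matrix(features)
  if (length(unique(outcome)) < 2) {
    warning("degenerate outcome: single class, tree has a single leaf")
    return(structure(list(rules = list(), tree = NULL), class = "tree_rules"))
  }
  df <- data.frame(..y = factor(outcome, levels = c(0, 1)), X,
                   check.names = TRUE)
  name_map <- stats::setNames(colnames(X), make.names(colnames(X)))
  fit <- rpart::rpart(..y ~ ., data = df, method = "class",
                      control = rpart::rpart.control(maxdepth = maxdepth,
                                                     cp = cp,
                                                     minbucket = minbucket))
  frame <- fit$frame
  leaves <- as.integer(rownames(frame)[frame$var == "<leaf>"])
  pos_leaves <- leaves[frame$yval[frame$var == "<leaf>"] == 2]
  if (nrow(frame) == 1) {
    warning("degenerate tree with a single leaf")
  }
  rules <- list()
  if (length(pos_leaves)) {
    paths <- rpart::path.rpart(fit, nodes = pos_leaves, print.it = FALSE)
    for (p in paths) {
      conds <- p[-1]  # drop "root"
      lits <- vapply(conds, function(cond) {
        neg <- grepl("< 0.5", cond, fixed = TRUE)
        var <- sub("(>=|<).*$", "", cond)
        var <- name_map[[trimws(var)]]
        if (neg) paste0("!", var) else var
      }, character(1))
      if (length(lits)) rules[[length(rules) + 1]] <- unname(lits)
    }
  }
  if (!length(rules)) warning("tree yields no positive leaf; empty rule set")
  structure(list(rules = rules, tree = fit), class = "tree_rules")
}

#' Random-forest variable importance
#'
#' Impurity-decrease (mean decrease in Gini) importance of every feature
#' from a bagged ensemble of classification trees, normalized to sum to 1
#' and ranked.
#'
#' @param features A `binary_features` object or 0/1 matrix.
#' @param outcome 0/1 outcome.
#' @param seed RNG seed.
#' @param ntree Number of trees (default 500).
#' @return data.frame with columns `feature`, `importance` (normalized),
#'   `rank`.
#' @export
forest_importance <- function(features, outcome, seed = 1, ntree = 500) {
  X <- feature_matrix(features)
  set.seed(seed)
  fit <- randomForest::randomForest(x = as.data.frame(X),
                                    y = factor(outcome, levels = c(0, 1)),
                                    ntree = ntree, importance = FALSE)
  imp <- randomForest::importance(fit, type = 2)[, 1]
  total <- sum(imp)
  norm <- if (total > 0) imp / total else imp
  out <- data.frame(feature = colnames(X), importance = unname(norm),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$importance, out$feature), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
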