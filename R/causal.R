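#' Assign treatment groups at mean + 1 SD
#'
#' Rows with the core variable strictly above its sample mean plus one
#' standard deviation form the high (treatment) group.
#'
#' @param values Numeric vector.
#' @return Integer 0/1 treatment indicator.
#' @export
assign_treatment <- function(values) {
  stopifnot(!anyNA(values))
  s <- stats::sd(values)
  t <- as.integer(values > mean(values) + s)
  if (all(t == 0) || all(t == 1)) {
    stop("degenerate treatment assignment: one group is empty")
  }
  t
}

#' Estimate propensity scores by logistic regression
#'
#' Maximum-likelihood logistic fit of treatment on the covariates;
#' scores are the inverse-logit of the linear predictor.
#'
#' @param W Covariate data.frame or matrix (may have zero columns for an
#'   intercept-only model).
#' @param treat 0/1 treatment indicator.
#' @return An object of class `propensity_model`: `coefficients`, `scores`,
#'   `covariates`, and the underlying `glm` fit.
#' @export
estimate_propensity <- function(W, treat) {
  W <- as.data.frame(W)
  stopifnot(all(treat %in% c(0, 1)))
  df <- cbind(data.frame(..treat = treat), W)
  fit <- suppressWarnings(
    stats::glm(..treat ~ ., data = df, family = stats::binomial()))
  p <- stats::fitted(fit)
  eps <- 1e-8
  if (any(p < eps | p > 1 - eps)) {
    cf <- stats::coef(fit)[-1]
    worst <- if (length(cf)) names(which.max(abs(cf))) else "(intercept)"
    stop("perfect or near-perfect separation in the propensity model; ",
         "largest coefficient on covariate '", worst, "'")
  }
  structure(list(coefficients = stats::coef(fit), scores = as.numeric(p),
                 covariates = colnames(W), fit = fit),
            class = "propensity_model")
}

#' Match treated to control rows on the propensity score
#'
#' * `nearest`: greedy 1:1 matching without replacement; treated rows are
#'   processed in descending score order, each paired with the unused
#'   control minimizing `|p_i - p_j|`, ties resolved to the lower row
#'   index.
#' * `caliper`: as `nearest`, but a pair is only formed when the distance
#'   is at most `caliper` (default 0.2 SD of the logit of the score).
#' * `radius`: every treated row is paired (with replacement) with all
#'   controls within `caliper`.
#'
#' @param scores Propensity scores in (0, 1).
#' @param treat 0/1 treatment indicator.
#' @param method `"nearest"`, `"radius"`, or `"caliper"`.
#' @param caliper Distance bound on the propensity-score scale; default
#'   `0.2 * sd(qlogis(scores))` for the caliper/radius methods.
#' @return An object of class `ps_match`: data.frame `pairs` (treated,
#'   control, distance) and the vector `unmatched_treated`.
#' @export
match_propensity <- function(scores, treat,
                             method = c("nearest", "radius", "caliper"),
                             caliper = NULL) {
  method <- match.arg(method)
  stopifnot(all(treat %in% c(0, 1)), all(scores > 0), all(scores < 1))
  treated <- which(treat == 1)
  controls <- which(treat == 0)
  if (!length(treated) || !length(controls)) {
    stop("both treatment groups must be non-empty")
  }
  if (is.null(caliper) && method %in% c("radius", "caliper")) {
    caliper <- 0.2 * stats::sd(stats::qlogis(scores))
  }
  pairs <- list()
  if (method == "radius") {
    for (i in treated) {
      d <- abs(scores[controls] - scores[i])
      hit <- which(d <= caliper)
      for (j in hit) {
        pairs[[length(pairs) + 1]] <- c(i, controls[j], d[j])
      }
    }
  } else {
    ord <- treated[order(-scores[treated], treated)]
    used <- logical(length(controls))
    for (i in ord) {
      avail <- which(!used)
      if (!length(avail)) break
      d <- abs(scores[controls[avail]] - scores[i])
      best <- avail[order(d, controls[avail])][1]
      bestd <- abs(scores[controls[best]] - scores[i])
      if (method == "caliper" && bestd > caliper) next
      used[best] <- TRUE
      pairs[[length(pairs) + 1]] <- c(i, controls[best], bestd)
    }
  }
  pairs_df <- if (length(pairs)) {
    df <- as.data.frame(do.call(rbind, pairs))
    names(df) <- c("treated", "control", "distance")
    df$treated <- as.integer(df$treated); df$control <- as.integer(df$control)
    df
  } else {
    warning("no pairs within the caliper")
    data.frame(treated = integer(0), control = integer(0),
               distance = numeric(0))
  }
  structure(list(pairs = pairs_df, method = method, caliper = caliper,
                 unmatched_treated = setdiff(treated, pairs_df$treated)),
            class = "ps_match")
}

#' Inverse probability weights
#'
#' `1/p` for treated rows, `1/(1-p)` for controls; weights above the 99th
#' percentile are flagged so extreme values can be inspected.
#'
#' @param scores Propensity scores strictly inside (0, 1).
#' @param treat 0/1 treatment indicator.
#' @return An object of class `ipw_weights`: numeric `weights` and integer
#'   indices `extreme` above the 99th percentile.
#' @export
ipw_weights <- function(scores, treat) {
  stopifnot(all(treat %in% c(0, 1)))
  if (any(scores <= 0 | scores >= 1)) {
    stop("propensity scores must lie strictly inside (0, 1)")
  }
  w <- ifelse(treat == 1, 1 / scores, 1 / (1 - scores))
  structure(list(weights = w,
                 extreme = which(w > stats::quantile(w, 0.99, type = 7))),
            class = "ipw_weights")
}

#' Mediation specification
#'
#' @param outcome Outcome column name (Y).
#' @param mediator Mediator column name (M).
#' @param treatment Treatment indicator column name, or `NULL` when the
#'   analysis runs ungrouped (the treatment term is then omitted from all
#'   three regressions).
#' @param controls Character vector of control column names (Z).
#' @param rules Character vector of rule-indicator column names.
#' @return An object of class `mediation_spec`.
#' @export
mediation_spec <- function(outcome, mediator, treatment = NULL,
                           controls = character(0), rules = character(0)) {
  roles <- c(outcome, mediator, treatment, controls, rules)
  if (anyDuplicated(roles)) {
    stop("a variable appears in two roles: ",
         paste(unique(roles[duplicated(roles)]), collapse = ", "))
  }
  structure(list(outcome = outcome, mediator = mediator,
                 treatment = treatment, controls = controls, rules = rules,
                 grouped = !is.null(treatment)),
            class = "mediation_spec")
}

coef_table <- function(fit) {
  s <- summary(fit)$coefficients
  data.frame(term = rownames(s), estimate = s[, 1], se = s[, 2],
             t = s[, 3], p = s[, 4], row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Fit the three mediation regressions
#'
#' Least-squares fits of (i) the mediator on the treatment indicator,
#' controls and rule indicators; (ii) the outcome on treatment, mediator
#' and controls; and (iii) the outcome on treatment, mediator, controls and
#' rule indicators. The indirect effect of each rule is the product of its
#' mediator-path coefficient from (i) and the mediator's outcome-path
#' coefficient from (iii), with a delta-method standard error; its direct
#' effect is its coefficient in (iii). When the spec is ungrouped the
#' treatment term is omitted everywhere.
#'
#' @param data data.frame holding all referenced columns (rule indicators
#'   typically built with [rule_cover()]).
#' @param spec A [mediation_spec()].
#' @param weights Optional observation weights (e.g. from [ipw_weights()]).
#' @return An object of class `mediation_result`: coefficient tables
#'   `eq_mediator`, `eq_outcome`, `eq_full`; data.frame `effects` (per rule:
#'   indirect, indirect_se, direct, direct_se); `vif` for the full model;
#'   `rule_overlap` correlation matrix of the indicators.
#' @export
mediation_fit <- function(data, spec, weights = NULL) {
  stopifnot(inherits(spec, "mediation_spec"))
  miss <- setdiff(c(spec$outcome, spec$mediator, spec$treatment,
                    spec$controls, spec$rules), names(data))
  if (length(miss)) stop("columns not in data: ", paste(miss, collapse = ", "))
  if (length(spec$rules) > 1) {
    R <- as.matrix(data[spec$rules])
    dup <- duplicated(t(R))
    if (any(dup)) {
      stop("rank-deficient design: duplicated rule indicator(s) ",
           paste(spec$rules[dup], collapse = ", "),
           "; merge identical rules before fitting")
    }
  }
  rhs <- function(terms) paste(terms, collapse = " + ")
  tr <- if (spec$grouped) spec$treatment else NULL
  f1 <- stats::as.formula(paste(spec$mediator, "~",
                                rhs(c(tr, spec$controls, spec$rules))))
  f2 <- stats::as.formula(paste(spec$outcome, "~",
                                rhs(c(tr, spec$mediator, spec$controls))))
  f3 <- stats::as.formula(paste(spec$outcome, "~",
                                rhs(c(tr, spec$mediator, spec$controls,
                                      spec$rules))))
  m1 <- stats::lm(f1, data = data, weights = weights)
  m2 <- stats::lm(f2, data = data, weights = weights)
  m3 <- stats::lm(f3, data = data, weights = weights)

  t1 <- coef_table(m1); t3 <- coef_table(m3)
  lam2 <- t3[t3$term == spec$mediator, ]
  effects <- do.call(rbind, lapply(spec$rules, function(r) {
    lr <- t1[t1$term == r, ]
    dr <- t3[t3$term == r, ]
    ind <- lr$estimate * lam2$estimate
    ind_se <- sqrt(lr$estimate^2 * lam2$se^2 + lam2$estimate^2 * lr$se^2)
    data.frame(rule = r, indirect = ind, indirect_se = ind_se,
               direct = dr$estimate, direct_se = dr$se,
               stringsAsFactors = FALSE)
  }))
  vif <- tryCatch({
    if (length(attr(stats::terms(m3), "term.labels")) >= 2) car::vif(m3) else NULL
  }, error = function(e) e$message)
  overlap <- if (length(spec$rules) > 1) {
    stats::cor(as.matrix(data[spec$rules]))
  } else NULL
  structure(list(eq_mediator = t1, eq_outcome = coef_table(m2),
                 eq_full = t3, effects = effects, vif = vif,
                 rule_overlap = overlap, spec = spec,
                 models = list(mediator = m1, outcome = m2, full = m3)),
            class = "mediation_result")
}

#' LASSO filtering of rule indicators
#'
#' Identical indicator columns are merged first (only the first of each
#' group enters the fit), then an L1-penalized regression of the outcome
#' on the indicators with a cross-validated penalty (`lambda.1se`) drops
#' rules whose coefficient shrinks to zero. Deterministic given the seed
#' (fold assignment is derived from it).
#'
#' @param indicators Matrix or data.frame of 0/1 rule indicators.
#' @param outcome Numeric or 0/1 outcome.
#' @param seed RNG seed for the cross-validation folds.
#' @param nfolds Number of CV folds.
#' @return Integer indices of retained rules (empty, with a warning, when
#'   everything is shrunk away).
#' @export
filter_rules_lasso <- function(indicators, outcome, seed = 1, nfolds = 10) {
  Xm <- as.matrix(indicators)
  if (ncol(Xm) < 1) stop("need at least one rule indicator")
  first_of_group <- !duplicated(t(Xm))
  Xm <- Xm[, first_of_group, drop = FALSE]
  orig_idx <- which(first_of_group)
  fam <- if (all(outcome %in% c(0, 1))) "binomial" else "gaussian"
  if (ncol(Xm) == 1) {
    # cv.glmnet needs >= 2 columns; test the single indicator directly
    p <- summary(stats::lm(outcome ~ Xm))$coefficients[2, 4]
    if (p < 0.05) return(unname(orig_idx[1]))
    warning("no rule indicator retained by the filter")
    return(integer(0))
  }
  set.seed(seed)
  foldid <- sample(rep(seq_len(nfolds), length.out = nrow(Xm)))
  cv <- glmnet::cv.glmnet(Xm, outcome, family = fam, foldid = foldid)
  cf <- as.matrix(stats::coef(cv, s = "lambda.1se"))[-1, 1]
  keep <- which(cf != 0)
  if (!length(keep)) warning("no rule indicator retained by the filter")
  unname(orig_idx[keep])
}
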