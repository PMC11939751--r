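make_table <- function(df, specs) {
  brsurvey:::new_survey_table(df, specs)
}

test_that("reverse coding flips flagged items and is an involution", {
  specs <- list(
    Sleepq = variable_spec("Sleepq", "ordinal", levels = 4, reverse_coded = TRUE),
    Selfd = variable_spec("Selfd", "ordinal", levels = 4, reverse_coded = TRUE),
    fair = variable_spec("fair", "ordinal", levels = 5)
  )
  tab <- make_table(data.frame(Sleepq = c(1, 4, 2), Selfd = c(2, 1, 3),
                               fair = c(5, 1, 3)), specs)
  out <- reverse_code(tab)
  # "1 = Very good" on the 1-4 sleep scale becomes the top construct score
  expect_equal(out$Sleepq, c(4, 1, 3))
  expect_equal(out$Selfd, c(3, 4, 2))
  expect_equal(out$fair, tab$fair)
  expect_equal(plain_df(reverse_code(out)), plain_df(tab))
  bad <- make_table(data.frame(Sleepq = c(0, 2, 3), Selfd = c(1, 1, 1),
                               fair = c(1, 1, 1)), specs)
  expect_error(reverse_code(bad), "level set")
})

test_that("the missingness filter drops variables then rows, monotonically in the threshold", {
  specs <- lapply(c("Jobs", "a", "b", "c"), function(nm)
    variable_spec(nm, "continuous", range = c(0, 100)))
  names(specs) <- c("Jobs", "a", "b", "c")
  set.seed(1)
  n <- 200
  df <- data.frame(Jobs = runif(n), a = runif(n), b = runif(n), c = runif(n))
  df$a[1:4] <- NA      # 2%
  df$b[1:14] <- NA     # 7%
  df$c[1:24] <- NA     # 12%
  tab <- make_table(df, specs)

  f10 <- filter_missing_variables(tab, 0.10)
  expect_setequal(names(f10), c("Jobs", "a", "b"))
  expect_false(anyNA(as.data.frame(f10)))
  f05 <- filter_missing_variables(tab, 0.05)
  expect_setequal(names(f05), c("Jobs", "a"))
  expect_true(all(setdiff(names(df), names(f10)) %in%
                  setdiff(names(df), names(f05))))

  clean <- make_table(df[complete.cases(df), ], specs)
  expect_equal(plain_df(filter_missing_variables(clean, 0.10)),
               plain_df(clean))

  df_bad <- df
  df_bad$Jobs[1:40] <- NA
  expect_error(filter_missing_variables(make_table(df_bad, specs), 0.10),
               "outcome")
})

test_that("work-time outlier removal keeps 84 and drops 85", {
  specs <- list(workt = variable_spec("workt", "continuous", range = c(0, 200)))
  tab <- make_table(data.frame(workt = c(10, 84, 85, 168, 40)), specs)
  out <- remove_outliers(tab)
  expect_equal(out$workt, c(10, 84, 40))
  ok <- make_table(data.frame(workt = c(0, 40, 84)), specs)
  expect_equal(plain_df(remove_outliers(ok)), plain_df(ok))
  expect_error(remove_outliers(make_table(data.frame(x = 1), list(
    x = variable_spec("x", "continuous", range = c(0, 1))))), "work-time")
})

test_that("outcome dichotomization thresholds at mean plus one SD", {
  v <- c(1, 2, 2, 3, 5)
  # mean 2.6, sd 1.5166 -> cutoff 4.1166; only the 5 exceeds it
  expect_equal(dichotomize_outcome(v), c(0L, 0L, 0L, 0L, 1L))
  expect_equal(dichotomize_outcome(v + 7), dichotomize_outcome(v))
  expect_warning(z <- dichotomize_outcome(rep(3, 6)), "zero variance")
  expect_equal(z, rep(0L, 6))
})

test_that("tercile discretization matches the quantile oracle and is rank-invariant", {
  v <- 1:9
  bins <- discretize_quantiles(v)
  expect_equal(bins, rep(1:3, each = 3))
  q <- quantile(v, c(1 / 3, 2 / 3), type = 7, names = FALSE)
  oracle <- 1L + (v > q[1]) + (v > q[2])
  expect_equal(bins, as.integer(oracle))

  set.seed(4)
  w <- rnorm(101)
  expect_equal(discretize_quantiles(w), discretize_quantiles(exp(w)))
  expect_warning(k <- discretize_quantiles(rep(2, 10)), "degenerate")
  expect_true(all(k == 1L))
})

test_that("binarization produces complementary, nested, overlapping features", {
  cfg <- tiny_sim(n = 300, seed = 17, noise = 0.1)
  tab <- generate_survey(cfg)
  bf <- prepare_survey(tab)
  X <- bf$X
  expect_true(all(X %in% c(0L, 1L)))
  expect_false(anyNA(X))
  base <- colnames(X)[!startsWith(colnames(X), "NOT_")]
  for (b in base) {
    expect_true(all(X[, b] + X[, paste0("NOT_", b)] == 1), label = b)
  }
  vars <- unique(bf$feature_info$variable[grepl("_low$", bf$feature_info$feature)])
  for (v in vars) {
    expect_true(all(X[, paste0(v, "_low")] <= X[, paste0(v, "_low_or_med")]),
                label = v)
    expect_true(all(X[, paste0(v, "_high")] <= X[, paste0(v, "_med_or_high")]),
                label = v)
    # a top-bin row: low = 0, low_or_med = 0, med_or_high = 1, high = 1
    top <- X[, paste0(v, "_high")] == 1
    if (any(top)) {
      expect_true(all(X[top, paste0(v, "_low")] == 0))
      expect_true(all(X[top, paste0(v, "_low_or_med")] == 0))
      expect_true(all(X[top, paste0(v, "_med_or_high")] == 1))
    }
    # complement identity: NOT_low_or_med picks out exactly the top bin
    expect_equal(unname(X[, paste0("NOT_", v, "_low_or_med")]),
                 unname(X[, paste0(v, "_high")]))
  }
  expect_false("Jobs" %in% bf$feature_info$variable)
})

test_that("preparation refuses tables that still contain missing values", {
  cfg <- tiny_sim(n = 100, seed = 23)
  tab <- generate_survey(cfg)
  tab$income[5] <- NA
  expect_error(binarize(reverse_code(tab)), "missing")
})
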