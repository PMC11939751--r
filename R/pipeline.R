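#' Read a survey table from CSV
#'
#' @param path CSV path (header = variable abbreviations).
#' @param specs A `survey_spec` describing the columns; columns absent
#'   from the spec are dropped with a message.
#' @return A `survey_table`.
#' @export
read_survey <- function(path, specs = default_survey_spec()) {
  df <- utils::read.csv(path, check.names = FALSE)
  known <- intersect(names(df), names(specs))
  extra <- setdiff(names(df), names(specs))
  if (length(extra)) {
    message("dropping undeclared column(s): ", paste(extra, collapse = ", "))
  }
  new_survey_table(df[, known, drop = FALSE], specs[known],
                   transforms = sprintf("read_survey(%s)", basename(path)))
}

#' Pipeline run configuration
#'
#' @param simulation A [simulation_config()], or `NULL` when `input_csv`
#'   points at an existing survey CSV.
#' @param input_csv Optional path to a survey CSV in the declared codings.
#' @param missing_threshold Variable missingness cutoff (0.10 default,
#'   0.05 for the robustness variant).
#' @param mining A [mining_config()].
#' @param prior,likelihood Rule-set prior and likelihood settings.
#' @param chains A [brs_chains()] used for the main fit.
#' @param bootstrap_B Number of stability resamples.
#' @param bootstrap_chains A [brs_chains()] used inside the bootstrap
#'   (typically lighter than the main fit).
#' @param prevalence_threshold Aggregation cutoff for the stability stage.
#' @param seed Master seed; per-stage child seeds are derived from it.
#' @return An object of class `run_config`.
#' @export
run_config <- function(simulation = NULL, input_csv = NULL,
                       missing_threshold = 0.10,
                       mining = mining_config(),
                       prior = brs_prior(), likelihood = brs_likelihood(),
                       chains = brs_chains(),
                       bootstrap_B = 100,
                       bootstrap_chains = brs_chains(n_chains = 5,
                                                     n_iters = 1000),
                       prevalence_threshold = 0.05, seed = 1) {
  if (is.null(simulation) && is.null(input_csv)) {
    stop("either a simulation config or an input CSV is required")
  }
  structure(list(simulation = simulation, input_csv = input_csv,
                 missing_threshold = missing_threshold, mining = mining,
                 prior = prior, likelihood = likelihood, chains = chains,
                 bootstrap_B = bootstrap_B,
                 bootstrap_chains = bootstrap_chains,
                 prevalence_threshold = prevalence_threshold,
                 seed = as.integer(seed)),
            class = "run_config")
}

derive_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) %% 1000003) * 1000 + stage)
}

#' Execute the full pipeline into a run directory
#'
#' Simulate (or ingest) the survey, prepare and binarize it, mine the
#' candidate pool, fit the rule set, run the bootstrap stability stage,
#' and write every artifact (tables as CSV/TSV, metadata as JSON) plus a
#' manifest with config echo, seeds and row/variable counts per stage.
#'
#' @param config A [run_config()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, `dir`; the manifest is `file.path(dir, "manifest.json")`.
#' @export
run_pipeline <- function(config, dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed,
                   missing_threshold = config$missing_threshold)

  stage <- "simulate/ingest"
  table <- tryCatch({
    if (!is.null(config$simulation)) {
      sim <- config$simulation
      sim$seed <- derive_seed(config$seed, 1L)
      generate_survey(sim)
    } else {
      read_survey(config$input_csv)
    }
  }, error = function(e) stop("stage '", stage, "' failed: ",
                              conditionMessage(e)))
  write_survey(table, file.path(dir, "survey.csv"))
  manifest$n_raw <- nrow(table)
  manifest$n_variables_raw <- ncol(table)

  stage <- "prep"
  bf <- tryCatch(
    prepare_survey(table, config$missing_threshold),
    error = function(e) stop("stage '", stage, "' failed: ",
                             conditionMessage(e)))
  prepared <- attr(bf, "table")
  manifest$n_prepared <- nrow(prepared)
  manifest$n_variables_prepared <- ncol(prepared)
  manifest$n_features <- ncol(bf$X)
  manifest$n_positive <- sum(bf$y)
  utils::write.csv(cbind(as.data.frame(bf$X), outcome = bf$y),
                   file.path(dir, "binary_matrix.csv"), row.names = FALSE)
  jsonlite::write_json(attr(prepared, "transforms"),
                       file.path(dir, "transform_log.json"), pretty = TRUE)

  stage <- "mine"
  pool <- tryCatch(
    mine_candidates(bf$X, bf$y, config$mining),
    error = function(e) stop("stage '", stage, "' failed: ",
                             conditionMessage(e)))
  manifest$pool_size <- nrow(pool)
  write_rule_pool(pool, file.path(dir, "rule_pool.tsv"))

  stage <- "fit"
  ch <- config$chains
  ch$seed <- derive_seed(config$seed, 2L)
  fit <- tryCatch(
    brs_fit(bf$X, bf$y, pool, config$prior, config$likelihood, ch),
    error = function(e) stop("stage '", stage, "' failed: ",
                             conditionMessage(e)))
  write_brs_fit(fit, file.path(dir, "fit.json"))
  manifest$map_rules <- vapply(fit$map_rules, rule_string, character(1))
  manifest$map_score <- fit$map_score

  stage <- "bootstrap"
  report <- tryCatch(
    bootstrap_stability(bf$X, bf$y, config$mining, config$bootstrap_chains,
                        config$prior, config$likelihood,
                        B = config$bootstrap_B,
                        seed = derive_seed(config$seed, 3L),
                        prevalence_threshold = config$prevalence_threshold),
    error = function(e) stop("stage '", stage, "' failed: ",
                             conditionMessage(e)))
  write_stability_report(report, file.path(dir, "stability.tsv"))
  edges <- interaction_edges(report)
  utils::write.table(edges, file.path(dir, "edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  labels_out <- classification_outcomes(report$aggregated, bf$X, bf$y)
  utils::write.table(data.frame(row = seq_along(labels_out),
                                outcome = as.character(labels_out)),
                     file.path(dir, "classification_labels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$aggregated_rules <- vapply(report$aggregated, rule_string,
                                      character(1))
  manifest$R_version <- as.character(getRversion())
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Compare two completed pipeline runs
#'
#' @param dir_a,dir_b Run directories produced by [run_pipeline()].
#' @return An object of class `run_comparison`: `jaccard` overlap of the
#'   aggregated rule sets and a side-by-side `prevalence` table.
#' @export
compare_runs <- function(dir_a, dir_b) {
  read_run <- function(dir) {
    mf <- file.path(dir, "manifest.json")
    st <- file.path(dir, "stability.tsv")
    if (!file.exists(mf) || !file.exists(st)) {
      stop("incomplete run directory: ", dir)
    }
    list(manifest = jsonlite::read_json(mf, simplifyVector = TRUE),
         stability = utils::read.delim(st, stringsAsFactors = FALSE))
  }
  a <- read_run(dir_a); b <- read_run(dir_b)
  ra <- a$manifest$aggregated_rules %||% character(0)
  rb <- b$manifest$aggregated_rules %||% character(0)
  union_n <- length(union(ra, rb))
  jac <- if (union_n == 0) 1 else length(intersect(ra, rb)) / union_n
  prev <- merge(a$stability[, c("rule", "prevalence")],
                b$stability[, c("rule", "prevalence")],
                by = "rule", all = TRUE, suffixes = c("_a", "_b"))
  structure(list(jaccard = jac, prevalence = prev,
                 aggregated_a = ra, aggregated_b = rb),
            class = "run_comparison")
}
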