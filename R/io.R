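#' Read pipeline CSV inputs
#'
#' Readers for the pipeline's delimited interchange formats (comma
#' separated, UTF-8, mandatory header row).  Response values are
#' case-insensitive `yes|no|unsure`; Section B values are `true|false`.
#' Malformed rows are reported with their line numbers.
#'
#' @param path CSV file path.
#' @return a validated data frame.
#' @name read_inputs
NULL

read_csv_checked <- function(path, required) {
  if (!file.exists(path)) stop_usage("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop_usage("%s: missing column(s): %s", path, paste(missing, collapse = ", "))
  df
}

check_response_col <- function(df, col, path) {
  v <- tolower(trimws(as.character(df[[col]])))
  bad <- which(!(v %in% RESPONSE_LEVELS))
  if (length(bad) > 0)
    stop_usage("%s: invalid %s value(s) at data line(s) %s (must be yes/no/unsure)",
               path, col, paste(utils::head(bad, 5L) + 1L, collapse = ", "))
  v
}

#' @rdname read_inputs
#' @export
read_responses <- function(path) {
  df <- read_csv_checked(path, c("child_id", "question_id",
                                 "parent_response", "investigator_response"))
  df$parent_response <- check_response_col(df, "parent_response", path)
  df$investigator_response <- check_response_col(df, "investigator_response", path)
  df$child_id <- as.character(df$child_id)
  df$question_id <- as.character(df$question_id)
  df
}

parse_logical_col <- function(df, col, path) {
  v <- tolower(trimws(as.character(df[[col]])))
  out <- ifelse(v %in% c("true", "t", "1"), TRUE,
                ifelse(v %in% c("false", "f", "0"), FALSE, NA))
  bad <- which(is.na(out))
  if (length(bad) > 0)
    stop_usage("%s: invalid %s value(s) at data line(s) %s (must be true/false)",
               path, col, paste(utils::head(bad, 5L) + 1L, collapse = ", "))
  out
}

#' @rdname read_inputs
#' @export
read_section_b <- function(path) {
  df <- read_csv_checked(path, c("child_id", B_ITEMS))
  for (col in B_ITEMS) df[[col]] <- parse_logical_col(df, col, path)
  df$child_id <- as.character(df$child_id)
  df
}

#' @rdname read_inputs
#' @export
read_covariates <- function(path) {
  df <- read_csv_checked(path, "child_id")
  df$child_id <- as.character(df$child_id)
  if (!is.null(df$expert_dsm5)) {
    v <- tolower(trimws(as.character(df$expert_dsm5)))
    bad <- which(!(v %in% c("positive", "negative")) & !is.na(df$expert_dsm5))
    if (length(bad) > 0)
      stop_usage("%s: expert_dsm5 must be positive/negative (bad line(s) %s)",
                 path, paste(utils::head(bad, 5L) + 1L, collapse = ", "))
    df$expert_dsm5 <- v
  }
  df
}

format_accuracy_text <- function(report, level) {
  c(sprintf("Diagnostic accuracy (exact %g%% confidence intervals)", 100 * level),
    sprintf("  %-12s %7s  [%7s to %7s]  (%d/%d)",
            report$measure,
            fmt_pct(report$point), fmt_pct(report$lower), fmt_pct(report$upper),
            report$num, report$den))
}

#' Score response files and write a per-child report
#'
#' Command-style wrapper over [score_cohort()]: reads the responses and
#' Section B CSVs, scores every child and writes the per-child score
#' report CSV (`child_id`, `total_score`, the seven subdomain flags,
#' `a2_abnormal_count`, `criteria_met_count`, `asd_positive`,
#' `severity_band`).
#'
#' @param responses_path,section_b_path input CSV paths.
#' @param out path of the report CSV to write.
#' @param instrument_path optional instrument definition; defaults to the
#'   shipped one.
#' @param cutoffs severity cutoffs (ASD, moderate, severe).
#' @return invisibly, the score report data frame.
#' @export
cmd_score <- function(responses_path, section_b_path, out,
                      instrument_path = NULL, cutoffs = c(10L, 11L, 14L)) {
  instrument <- if (is.null(instrument_path)) default_instrument()
                else load_instrument(instrument_path)
  responses <- read_responses(responses_path)
  section_b <- read_section_b(section_b_path)
  report <- score_cohort(responses, section_b, instrument, cutoffs)
  dir.create(dirname(out), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report, out, row.names = FALSE)
  message(sprintf("scored %d children -> %s (%d tool-positive)",
                  nrow(report), out, sum(report$asd_positive)))
  invisible(report)
}

#' Validate a score report against a reference diagnosis
#'
#' Command-style wrapper over the accuracy module: joins the score report
#' with the covariates table on `child_id`, builds the 2x2 table of tool
#' calls against the expert DSM-5 reference, and writes the accuracy
#' report (four measures with exact CIs) as CSV and aligned text.  When
#' CARS scores are available it also writes the severity cross-tab, and
#' the ROC of the total score against the reference with its
#' Youden-optimal cutoff.
#'
#' @param scores_path score report CSV from [cmd_score()].
#' @param covariates_path covariates CSV with `expert_dsm5` (and
#'   optionally `cars_score`).
#' @param out_dir directory for the report files.
#' @param level confidence level for the exact intervals.
#' @return invisibly, a list with `confusion`, `accuracy`, `cross_tab`
#'   (or NULL), `roc` (or NULL).
#' @export
cmd_validate <- function(scores_path, covariates_path, out_dir, level = 0.95) {
  scores <- read_csv_checked(scores_path, c("child_id", "total_score", "asd_positive"))
  scores$child_id <- as.character(scores$child_id)
  scores$asd_positive <- parse_logical_col(scores, "asd_positive", scores_path)
  cov <- read_covariates(covariates_path)
  if (is.null(cov$expert_dsm5))
    stop_usage("%s: no expert_dsm5 reference labels; cannot validate", covariates_path)

  idx <- match(scores$child_id, cov$child_id)
  if (anyNA(idx))
    stop_usage("covariates missing for child(ren): %s",
               paste(utils::head(scores$child_id[is.na(idx)], 5L), collapse = ", "))
  ref <- cov$expert_dsm5[idx] == "positive"
  if (length(unique(ref)) < 2L)
    stop_usage("reference diagnosis has a single class; accuracy is undefined")

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ct <- confusion_table(scores$asd_positive, ref)
  acc <- accuracy_report(ct, level)
  utils::write.csv(acc, file.path(out_dir, "accuracy.csv"), row.names = FALSE)
  writeLines(format_accuracy_text(acc, level), file.path(out_dir, "accuracy.txt"))

  xtab <- NULL
  roc <- NULL
  if (!is.null(cov$cars_score)) {
    xtab <- cross_tab_severity(scores$asd_positive, as.numeric(cov$cars_score[idx]))
    utils::write.csv(xtab, file.path(out_dir, "cars_cross_tab.csv"), row.names = FALSE)
  }
  roc <- roc_curve(scores$total_score, ref)
  utils::write.csv(roc$points, file.path(out_dir, "roc_points.csv"), row.names = FALSE)

  message(sprintf(
    "validated %d children: sensitivity %s, specificity %s; Youden cutoff >= %g (AUC %.3f)",
    ct$n, fmt_pct(acc$point[acc$measure == "sensitivity"]),
    fmt_pct(acc$point[acc$measure == "specificity"]),
    roc$youden_cutoff, roc$auc))
  invisible(list(confusion = ct, accuracy = acc, cross_tab = xtab, roc = roc))
}

#' Simulate a cohort and write its files
#'
#' Command-style wrapper over [simulate_cohort()] and [write_cohort()].
#'
#' @param out_dir directory for the cohort CSVs.
#' @param params a [cohort_params()] object; `seed` and `n` override its
#'   fields when given.
#' @param seed,n optional overrides.
#' @return invisibly, the simulated cohort.
#' @export
cmd_simulate <- function(out_dir, params = cohort_params(), seed = NULL, n = NULL) {
  if (!is.null(seed)) params$seed <- as.integer(seed)
  if (!is.null(n)) params$n <- as.integer(n)
  validate_cohort_params(params)
  cohort <- simulate_cohort(params)
  write_cohort(cohort, out_dir)
  prev <- mean(cohort$truth$latent_class)
  bands <- table(factor(cars_band(cohort$truth$cars_score), levels = CARS_BANDS))
  message(sprintf(
    "simulated %d children (seed %d) -> %s; realized prevalence %.3f; CARS bands %s",
    params$n, params$seed, out_dir, prev,
    paste(sprintf("%s=%d", names(bands), as.integer(bands)), collapse = ", ")))
  invisible(cohort)
}
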