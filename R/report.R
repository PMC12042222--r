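workflow_result_to_list <- function(result, summary = NULL, capacity = NULL) {
  strata <- lapply(c(sm = "sm", dbt = "dbt", total = "total"), function(s) {
    row <- result_row(result, s)
    as.list(row[setdiff(names(row), "stratum")])
  })
  out <- list(spec = result$spec,
              cohort_size = result$cohort_size,
              reference_cancers = result$reference_cancers,
              strata = strata)
  if (!is.null(summary)) out$summary <- as.list(summary)
  if (!is.null(capacity)) out$capacity <- unclass(capacity)
  out
}

as_workflow_result <- function(x) {
  strata <- lapply(x$strata, tibble::as_tibble)
  summary <- do.call(rbind, strata)
  summary <- tibble::add_column(summary, stratum = names(x$strata), .before = 1L)
  structure(list(summary = summary, spec = x$spec,
                 cohort_size = x$cohort_size,
                 reference_cancers = x$reference_cancers),
            class = "workflow_result")
}

#' Render a workflow result as a plain-text and JSON report
#'
#' Produces a human-readable table mirroring the published per-stratum
#' layout (SM, DBT and Total rows; read examinations, workload, recalls,
#' false-positive recalls, detected and non-detected cancers) together with
#' a machine-readable list carrying the same numbers, optionally extended
#' with the baseline comparison and the clinic FTE report.
#'
#' @param result A [evaluate_workflow()] result.
#' @param summary Optional [summarize_vs_baseline()] row.
#' @param capacity Optional [estimate_fte()] report.
#' @param path_text,path_json Optional output paths; when given, the text
#'   rendering / the JSON rendering is written there.
#' @return Invisibly, a list with `text` (character vector of lines) and
#'   `data` (the JSON-able list).
#' @export
render_report <- function(result, summary = NULL, capacity = NULL,
                          path_text = NULL, path_json = NULL) {
  stopifnot(inherits(result, "workflow_result"))
  data <- workflow_result_to_list(result, summary, capacity)
  fmt <- function(s) {
    row <- result_row(result, s)
    sprintf("%-6s %14d %12.1f %9d %12d %10d %14d",
            toupper(s), row$read_exams, row$workload, row$recalls,
            row$fp_recalls, row$detected, row$non_detected)
  }
  text <- c(
    sprintf("Workflow %s / %s, threshold %.2f, DBT:SM ratio %.2f",
            toupper(result$spec$low_arm), toupper(result$spec$high_arm),
            result$spec$threshold, result$spec$ratio),
    sprintf("Cohort %d examinations, %d reference cancers",
            result$cohort_size, result$reference_cancers),
    sprintf("%-6s %14s %12s %9s %12s %10s %14s", "",
            "read_exams", "workload", "recalls", "fp_recalls",
            "detected", "non_detected"),
    fmt("sm"), fmt("dbt"), fmt("total"))
  if (!is.null(summary)) {
    text <- c(text, sprintf(
      paste0("Detection %+d%% vs baseline; %d%% of DBT-DR-detectable; ",
             "workload %+d%% vs baseline; %.2f detected per 1000 screened"),
      summary$pct_more_detected, summary$pct_of_dbt_detectable,
      summary$pct_workload_change, summary$rate_per_1000))
  }
  if (!is.null(capacity)) {
    text <- c(text, sprintf(
      "FTE: reading %.2f + recall workup %.2f + referrals %.2f = %.2f total",
      capacity$fte_screen_reading, capacity$fte_recall_workup,
      capacity$fte_referrals, capacity$fte_total))
  }
  if (!is.null(path_text)) writeLines(text, path_text)
  if (!is.null(path_json)) {
    jsonlite::write_json(data, path_json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(list(text = text, data = data))
}
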