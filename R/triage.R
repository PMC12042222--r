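READING_ARMS <- c("sr-sm", "dr-sm", "sr-dbt", "dr-dbt")

arm_check <- function(arm) {
  if (!is.character(arm) || length(arm) != 1L || !arm %in% READING_ARMS) {
    stop("reading arm must be one of: ", paste(READING_ARMS, collapse = ", "),
         call. = FALSE)
  }
  arm
}

arm_modality <- function(arm) if (grepl("dbt$", arm_check(arm))) "dbt" else "sm"
arm_readers <- function(arm) if (grepl("^dr", arm_check(arm))) 2L else 1L
arm_recall_col <- function(arm) {
  paste0("recall_", arm_modality(arm), "_", if (arm_readers(arm) == 2L) "dr" else "sr")
}

#' Reading-time equivalents of one examination under a reading arm
#'
#' Workload is expressed in reading-time equivalents where single reading
#' one SM examination costs 1 unit and one DBT read costs `ratio` units (the
#' DBT:SM reading-time ratio; previous reading-time studies put it near 2,
#' with 1.7 as a less conservative alternative). Double reading doubles the
#' cost, so with the default ratio the four arms cost 1, 2, 2 and 4 units.
#'
#' @param arm One of `"sr-sm"`, `"dr-sm"`, `"sr-dbt"`, `"dr-dbt"` (single or
#'   double reading of synthetic mammography or tomosynthesis).
#' @param ratio DBT:SM reading-time ratio, positive.
#' @return Reading-time equivalents per examination (real).
#' @examples
#' arm_units("dr-dbt")            # 4
#' arm_units("dr-dbt", ratio = 1.7) # 3.4
#' @export
arm_units <- function(arm, ratio = 2) {
  stopifnot(is.numeric(ratio), length(ratio) == 1L, ratio > 0)
  base <- if (arm_modality(arm) == "dbt") ratio else 1
  arm_readers(arm) * base
}

stratum_summary <- function(sub, arm, ratio) {
  flag <- sub[[arm_recall_col(arm)]]
  detected <- sum(flag & sub$cancer)
  tibble::tibble(
    read_exams = nrow(sub),
    workload = nrow(sub) * arm_units(arm, ratio),
    recalls = sum(flag),
    fp_recalls = sum(flag & !sub$cancer),
    detected = detected,
    non_detected = sum(sub$cancer) - detected)
}

#' Evaluate a triage workflow on a cohort at one threshold
#'
#' Stratifies the cohort at the AI-score threshold — examinations scoring at
#' or above it form the high-risk DBT stratum, the rest the low-risk SM
#' stratum — and applies the stratum's reading arm to every examination in
#' it. Per stratum it reports read examinations, workload in reading-time
#' equivalents, recalls, false-positive recalls, detected cancers, and
#' non-detected cancers (reference cancers whose score places them in the
#' stratum but that the stratum's arm does not recall); totals are
#' componentwise sums.
#'
#' @param cohort A cohort table (see [as_cohort()]).
#' @param low_arm SM reading arm for the low-risk stratum (`"sr-sm"` or
#'   `"dr-sm"`).
#' @param high_arm DBT reading arm for the high-risk stratum (`"sr-dbt"` or
#'   `"dr-dbt"`).
#' @param threshold AI-score threshold in \eqn{[0, 10]}; ties go to the DBT
#'   stratum ("score of `threshold` or higher").
#' @param ratio DBT:SM reading-time ratio (see [arm_units()]).
#' @param reference_cancers Size of the reference cancer set used for the
#'   total non-detected count; defaults to the number of cancers in the
#'   cohort.
#' @return An object of class `workflow_result`: a list with `summary` (a
#'   tibble with rows `sm`, `dbt`, `total` and the six stratum columns),
#'   `spec` (arms, threshold, ratio), `cohort_size` and `reference_cancers`.
#' @examples
#' fx <- build_fixture_cohort()
#' evaluate_workflow(fx, "sr-sm", "dr-dbt", threshold = 5)$summary
#' @export
evaluate_workflow <- function(cohort, low_arm = "sr-sm", high_arm = "dr-dbt",
                              threshold, ratio = 2,
                              reference_cancers = NULL) {
  validate_cohort(cohort)
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      is.na(threshold) || threshold < 0 || threshold > 10) {
    stop("threshold must be a single value in [0, 10]", call. = FALSE)
  }
  if (arm_modality(low_arm) != "sm") {
    stop("low_arm must read SM (sr-sm or dr-sm)", call. = FALSE)
  }
  if (arm_modality(high_arm) != "dbt") {
    stop("high_arm must read DBT (sr-dbt or dr-dbt)", call. = FALSE)
  }
  reference_cancers <- reference_cancers %||% sum(cohort$cancer)
  high <- cohort$ai_score >= threshold
  sm <- stratum_summary(cohort[!high, , drop = FALSE], low_arm, ratio)
  dbt <- stratum_summary(cohort[high, , drop = FALSE], high_arm, ratio)
  total <- sm + dbt
  if (reference_cancers < total$detected) {
    stop(sprintf("reference_cancers (%d) is smaller than detected cancers (%d)",
                 reference_cancers, total$detected), call. = FALSE)
  }
  total$non_detected <- reference_cancers - total$detected
  summary <- rbind(sm, dbt, total)
  summary <- tibble::add_column(summary, stratum = c("sm", "dbt", "total"),
                                .before = 1L)
  structure(
    list(summary = summary,
         spec = list(low_arm = low_arm, high_arm = high_arm,
                     threshold = threshold, ratio = ratio),
         cohort_size = nrow(cohort),
         reference_cancers = reference_cancers),
    class = "workflow_result")
}

#' @export
print.workflow_result <- function(x, ...) {
  cat(sprintf("<workflow_result> %s / %s at threshold %.2f (ratio %.2g)\n",
              toupper(x$spec$low_arm), toupper(x$spec$high_arm),
              x$spec$threshold, x$spec$ratio))
  print(as.data.frame(x$summary), row.names = FALSE)
  invisible(x)
}

result_row <- function(result, stratum) {
  result$summary[result$summary$stratum == stratum, , drop = FALSE]
}

#' Sweep AI-score thresholds over all four workflow combinations
#'
#' Evaluates every combination of low-risk SM arm (single or double reading)
#' and high-risk DBT arm at each point of a threshold grid, yielding the
#' workload, recall and cancer-detection curves as functions of the
#' threshold. At threshold 0 every examination is in the DBT stratum; above
#' the maximum score, every examination is SM-read.
#'
#' @inheritParams evaluate_workflow
#' @param grid Sorted numeric grid of thresholds within \eqn{[0, 10]};
#'   the default 0.05 step stands in for a continuously varied threshold.
#' @return A tibble with one row per (threshold, workflow) and columns
#'   `threshold`, `low_arm`, `high_arm`, `workflow` (display label),
#'   `read_dbt`, `workload`, `recalls`, `fp_recalls`, `detected`.
#' @export
sweep_thresholds <- function(cohort, grid = seq(0, 10, by = 0.05), ratio = 2,
                             reference_cancers = NULL) {
  if (is.unsorted(grid) || any(grid < 0 | grid > 10)) {
    stop("grid must be sorted and within [0, 10]", call. = FALSE)
  }
  combos <- expand.grid(low_arm = c("sr-sm", "dr-sm"),
                        high_arm = c("sr-dbt", "dr-dbt"),
                        stringsAsFactors = FALSE)
  rows <- lapply(grid, function(th) {
    per_combo <- lapply(seq_len(nrow(combos)), function(i) {
      res <- evaluate_workflow(cohort, combos$low_arm[i], combos$high_arm[i],
                               threshold = th, ratio = ratio,
                               reference_cancers = reference_cancers)
      tot <- result_row(res, "total")
      tibble::tibble(threshold = th,
                     low_arm = combos$low_arm[i], high_arm = combos$high_arm[i],
                     workflow = paste(toupper(sub("-", " ", combos$low_arm[i])),
                                      toupper(sub("-", " ", combos$high_arm[i])),
                                      sep = "/"),
                     read_dbt = result_row(res, "dbt")$read_exams,
                     workload = tot$workload, recalls = tot$recalls,
                     fp_recalls = tot$fp_recalls, detected = tot$detected)
    })
    do.call(rbind, per_combo)
  })
  do.call(rbind, rows)
}

#' High-risk fraction giving workload parity with a baseline
#'
#' Solves for the fraction \eqn{p^*} of examinations triaged to the
#' high-risk DBT arm at which total per-examination workload
#' \eqn{a(1-p) + bp} equals a baseline (default 2 units per examination,
#' i.e. uniform double-read SM/DM), where \eqn{a} and \eqn{b} are the
#' per-examination reading-time equivalents of the two arms. With single-read
#' SM and double-read DBT at ratio 2 this gives \eqn{p^* = 1/3}: double-read
#' the highest-risk third and workload matches double-reading everyone on SM.
#'
#' @inheritParams evaluate_workflow
#' @param baseline_units_per_exam Baseline workload per examination.
#' @return The fraction \eqn{p^*} in \eqn{[0, 1]}, or `NA` if the two arms
#'   cost the same (workload is threshold-independent) or the solution falls
#'   outside \eqn{[0, 1]}.
#' @examples
#' workload_neutral_fraction("sr-sm", "dr-dbt")              # 1/3
#' workload_neutral_fraction("dr-sm", "sr-dbt")              # NA (flat curve)
#' @export
workload_neutral_fraction <- function(low_arm, high_arm, ratio = 2,
                                      baseline_units_per_exam = 2) {
  stopifnot(baseline_units_per_exam > 0)
  a <- arm_units(low_arm, ratio)
  b <- arm_units(high_arm, ratio)
  if (isTRUE(all.equal(a, b))) return(NA_real_)
  p <- (baseline_units_per_exam - a) / (b - a)
  if (p < 0 || p > 1) NA_real_ else p
}

#' Round half away from zero
#'
#' Reported percentages and rates use conventional half-up rounding rather
#' than R's round-half-to-even.
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Compare a workflow result with a uniform-reading baseline
#'
#' Derives the headline comparison figures for a triage workflow: percent
#' change in detected cancers versus a baseline reading strategy (by default
#' uniform SM/DM double reading), the percent of DBT-double-reading-
#' detectable cancers found, percent workload change, and the cancer
#' detection rate per 1000 screened women. Percents are rounded half-up to
#' integers, the rate to two decimals.
#'
#' @param result A [evaluate_workflow()] result.
#' @param baseline_detected Cancers detected by the baseline strategy.
#' @param baseline_workload Baseline workload in reading-time equivalents;
#'   defaults to double-reading SM for the whole cohort (2 units each).
#' @param dbt_dr_detected Cancers detectable by uniform DBT double reading.
#' @param n_exams Number of screened women; defaults to the result's cohort.
#' @return A tibble with columns `detected`, `pct_more_detected`,
#'   `pct_of_dbt_detectable`, `pct_workload_change`, `rate_per_1000`.
#' @examples
#' fx <- build_fixture_cohort()
#' res <- evaluate_workflow(fx, "sr-sm", "dr-dbt", threshold = 5)
#' summarize_vs_baseline(res)
#' @export
summarize_vs_baseline <- function(result,
                                  baseline_detected = 95,
                                  baseline_workload = 2 * result$cohort_size,
                                  dbt_dr_detected = 127,
                                  n_exams = result$cohort_size) {
  stopifnot(inherits(result, "workflow_result"))
  if (baseline_detected <= 0 || baseline_workload <= 0 ||
      dbt_dr_detected <= 0 || n_exams <= 0) {
    stop("baselines and denominators must be positive", call. = FALSE)
  }
  tot <- result_row(result, "total")
  tibble::tibble(
    detected = tot$detected,
    pct_more_detected =
      round_half_up(100 * (tot$detected - baseline_detected) / baseline_detected),
    pct_of_dbt_detectable =
      round_half_up(100 * tot$detected / dbt_dr_detected),
    pct_workload_change =
      round_half_up(100 * (tot$workload - baseline_workload) / baseline_workload),
    rate_per_1000 = round_half_up(1000 * tot$detected / n_exams, 2))
}
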