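#' Clinic parameters for the workforce capacity model
#'
#' Assumptions describing an example breast radiology clinic, used to
#' translate a screening workflow into full-time-equivalent (FTE)
#' radiologist requirements. Defaults: 68,000 screening examinations per
#' year, reading times of 40 s per SM/DM read and 80 s per DBT read, a
#' workup capacity of 20 recalled or clinically referred women per
#' radiologist-day (shared by recalls and referrals), 10,500 symptomatic
#' referrals per year, and a 40-hour working week. The annual calendar —
#' 45 working weeks (1800 h) and 225 working days — is not part of the
#' published assumptions and is configurable.
#'
#' @param annual_screens Screening examinations per year.
#' @param read_seconds_sm,read_seconds_dbt Seconds per single read.
#' @param workup_capacity Recalled or referred women per radiologist-day.
#' @param annual_referrals Clinical (non-screening) referrals per year.
#' @param weekly_hours Working hours per week.
#' @param working_days_per_year,working_weeks_per_year Annual calendar.
#' @return An object of class `clinic_params`.
#' @export
clinic_params <- function(annual_screens = 68000,
                          read_seconds_sm = 40,
                          read_seconds_dbt = 80,
                          workup_capacity = 20,
                          annual_referrals = 10500,
                          weekly_hours = 40,
                          working_days_per_year = 225,
                          working_weeks_per_year = 45) {
  p <- list(annual_screens = annual_screens,
            read_seconds_sm = read_seconds_sm,
            read_seconds_dbt = read_seconds_dbt,
            workup_capacity = workup_capacity,
            annual_referrals = annual_referrals,
            weekly_hours = weekly_hours,
            working_days_per_year = working_days_per_year,
            working_weeks_per_year = working_weeks_per_year)
  bad <- names(p)[!vapply(p, function(v)
    is.numeric(v) && length(v) == 1L && is.finite(v) && v > 0, logical(1))]
  if (length(bad)) {
    stop("clinic parameter(s) must be single positive numbers: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(p, class = "clinic_params")
}

#' Annual screen-reading time for a workflow
#'
#' Scales the stratum proportions of an evaluated workflow to the clinic's
#' annual screening volume and prices each stratum at its per-read seconds
#' times its number of readers: `annual_screens * (share_sm * readers_sm *
#' read_seconds_sm + share_dbt * readers_dbt * read_seconds_dbt)`.
#'
#' @param result A [evaluate_workflow()] result (its `spec` carries the
#'   reading arms, its `summary` the stratum sizes).
#' @param clinic A [clinic_params()] object.
#' @return Annual reading time in seconds.
#' @export
annual_reading_seconds <- function(result, clinic) {
  stopifnot(inherits(result, "workflow_result"), inherits(clinic, "clinic_params"))
  share_sm <- result_row(result, "sm")$read_exams / result$cohort_size
  share_dbt <- result_row(result, "dbt")$read_exams / result$cohort_size
  clinic$annual_screens *
    (share_sm * arm_readers(result$spec$low_arm) * clinic$read_seconds_sm +
     share_dbt * arm_readers(result$spec$high_arm) * clinic$read_seconds_dbt)
}

#' Full-time-equivalent radiologist requirements for a workflow
#'
#' Converts a workflow's reading volumes and recall rate into the number of
#' FTE breast radiologists needed for three tasks: screen reading (annual
#' reading seconds divided by annual working hours), workup of women
#' recalled from screening (annual recalls divided by daily workup capacity
#' times working days), and workup of symptomatic clinical referrals (same
#' capacity; independent of the screening workflow). Also reports detection
#' relative to uniform DBT double reading.
#'
#' @inheritParams annual_reading_seconds
#' @param dbt_dr_detected Cancers detectable by uniform DBT double reading
#'   (denominator of `relative_detection`).
#' @return An object of class `clinic_report` with fields
#'   `fte_screen_reading`, `fte_recall_workup`, `fte_referrals`,
#'   `fte_total`, `relative_detection`.
#' @examples
#' fx <- build_fixture_cohort()
#' res <- evaluate_workflow(fx, "sr-sm", "dr-dbt", threshold = 5)
#' estimate_fte(res, clinic_params())
#' @export
estimate_fte <- function(result, clinic, dbt_dr_detected = 127) {
  stopifnot(inherits(result, "workflow_result"), inherits(clinic, "clinic_params"))
  if (dbt_dr_detected <= 0) {
    stop("dbt_dr_detected must be positive", call. = FALSE)
  }
  annual_hours <- clinic$weekly_hours * clinic$working_weeks_per_year
  workups_per_year <- clinic$workup_capacity * clinic$working_days_per_year
  tot <- result_row(result, "total")
  annual_recalls <- clinic$annual_screens * tot$recalls / result$cohort_size
  rep <- list(
    fte_screen_reading = annual_reading_seconds(result, clinic) /
      (annual_hours * 3600),
    fte_recall_workup = annual_recalls / workups_per_year,
    fte_referrals = clinic$annual_referrals / workups_per_year,
    relative_detection = tot$detected / dbt_dr_detected)
  rep$fte_total <- rep$fte_screen_reading + rep$fte_recall_workup +
    rep$fte_referrals
  structure(rep, class = "clinic_report")
}

#' @export
print.clinic_report <- function(x, ...) {
  cat("<clinic_report>\n")
  cat(sprintf("  FTE screen reading : %6.2f\n", x$fte_screen_reading))
  cat(sprintf("  FTE recall workup  : %6.2f\n", x$fte_recall_workup))
  cat(sprintf("  FTE referrals      : %6.2f\n", x$fte_referrals))
  cat(sprintf("  FTE total          : %6.2f\n", x$fte_total))
  cat(sprintf("  relative detection : %6.1f%% of uniform DBT double reading\n",
              100 * x$relative_detection))
  invisible(x)
}
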