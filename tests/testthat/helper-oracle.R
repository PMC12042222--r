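# Independent oracle: per-record accumulation loop, written without reusing
# the package's stratum grouping or arm helpers.
oracle_evaluate <- function(cohort, low_arm, high_arm, threshold, ratio = 2) {
  df <- as.data.frame(cohort)
  units <- list("sr-sm" = 1, "dr-sm" = 2,
                "sr-dbt" = ratio, "dr-dbt" = 2 * ratio)
  cols <- list("sr-sm" = "recall_sm_sr", "dr-sm" = "recall_sm_dr",
               "sr-dbt" = "recall_dbt_sr", "dr-dbt" = "recall_dbt_dr")
  acc <- list(sm = c(read = 0, work = 0, rec = 0, fp = 0, det = 0, nondet = 0),
              dbt = c(read = 0, work = 0, rec = 0, fp = 0, det = 0, nondet = 0))
  for (i in seq_len(nrow(df))) {
    stratum <- if (df$ai_score[i] >= threshold) "dbt" else "sm"
    arm <- if (stratum == "dbt") high_arm else low_arm
    recalled <- df[[cols[[arm]]]][i]
    a <- acc[[stratum]]
    a["read"] <- a["read"] + 1
    a["work"] <- a["work"] + units[[arm]]
    if (recalled) a["rec"] <- a["rec"] + 1
    if (recalled && !df$cancer[i]) a["fp"] <- a["fp"] + 1
    if (recalled && df$cancer[i]) a["det"] <- a["det"] + 1
    if (!recalled && df$cancer[i]) a["nondet"] <- a["nondet"] + 1
    acc[[stratum]] <- a
  }
  acc$total <- acc$sm + acc$dbt
  acc
}

expect_matches_oracle <- function(cohort, low_arm, high_arm, threshold,
                                  ratio = 2) {
  got <- evaluate_workflow(cohort, low_arm, high_arm, threshold = threshold,
                           ratio = ratio)
  want <- oracle_evaluate(cohort, low_arm, high_arm, threshold, ratio)
  for (s in c("sm", "dbt", "total")) {
    row <- got$summary[got$summary$stratum == s, ]
    expect_equal(
      c(row$read_exams, row$workload, row$recalls, row$fp_recalls,
        row$detected, row$non_detected),
      unname(want[[s]]),
      label = sprintf("stratum %s at threshold %.2f (%s/%s)",
                      s, threshold, low_arm, high_arm))
  }
}

# small random cohorts for property tests; nesting holds by construction
random_cohort <- function(n, seed) {
  set.seed(seed)
  sm_dr <- runif(n) < 0.15
  dbt_dr <- runif(n) < 0.2
  as_cohort(tibble::tibble(
    exam_id = paste0("r", seq_len(n)),
    ai_score = runif(n, 0, 10),
    cancer = runif(n) < 0.05,
    recall_sm_sr = sm_dr & runif(n) < 0.7,
    recall_sm_dr = sm_dr,
    recall_dbt_sr = dbt_dr & runif(n) < 0.8,
    recall_dbt_dr = dbt_dr),
    provenance = paste0("random:", seed))
}
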