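# Published per-stratum worked examples at thresholds 5 and 7 (ratio r = 2),
# frozen cell-for-cell. Columns: read examinations, workload (reading-time
# equivalents), recalls, false-positive recalls, detected, non-detected.
expected_cells <- function() {
  tb <- tibble::tribble(
    ~threshold, ~low_arm, ~high_arm, ~stratum, ~read_exams, ~workload, ~recalls, ~fp_recalls, ~detected, ~non_detected,
    5, "sr-sm", "sr-dbt", "sm",    10320, 10320, 107, 101,   6,  7,
    5, "sr-sm", "sr-dbt", "dbt",    4452,  8904, 281, 176, 105, 17,
    5, "sr-sm", "sr-dbt", "total", 14772, 19224, 388, 277, 111, 24,
    5, "sr-sm", "dr-dbt", "sm",    10320, 10320, 107, 101,   6,  7,
    5, "sr-sm", "dr-dbt", "dbt",    4452, 17808, 327, 211, 116,  6,
    5, "sr-sm", "dr-dbt", "total", 14772, 28128, 434, 312, 122, 13,
    5, "dr-sm", "sr-dbt", "sm",    10320, 20640, 145, 136,   9,  4,
    5, "dr-sm", "sr-dbt", "dbt",    4452,  8904, 281, 176, 105, 17,
    5, "dr-sm", "sr-dbt", "total", 14772, 29544, 426, 312, 114, 21,
    5, "dr-sm", "dr-dbt", "sm",    10320, 20640, 145, 136,   9,  4,
    5, "dr-sm", "dr-dbt", "dbt",    4452, 17808, 327, 211, 116,  6,
    5, "dr-sm", "dr-dbt", "total", 14772, 38448, 472, 347, 125, 10,
    7, "sr-sm", "sr-dbt", "sm",    11505, 11505, 131, 123,   8,  9,
    7, "sr-sm", "sr-dbt", "dbt",    3267,  6534, 252, 151, 101, 17,
    7, "sr-sm", "sr-dbt", "total", 14772, 18039, 383, 274, 109, 26,
    7, "sr-sm", "dr-dbt", "sm",    11505, 11505, 131, 123,   8,  9,
    7, "sr-sm", "dr-dbt", "dbt",    3267, 13068, 288, 176, 112,  6,
    7, "sr-sm", "dr-dbt", "total", 14772, 24573, 419, 299, 120, 15,
    7, "dr-sm", "sr-dbt", "sm",    11505, 23010, 177, 165,  12,  5,
    7, "dr-sm", "sr-dbt", "dbt",    3267,  6534, 252, 151, 101, 17,
    7, "dr-sm", "sr-dbt", "total", 14772, 29544, 429, 316, 113, 22,
    7, "dr-sm", "dr-dbt", "sm",    11505, 23010, 177, 165,  12,  5,
    7, "dr-sm", "dr-dbt", "dbt",    3267, 13068, 288, 176, 112,  6,
    7, "dr-sm", "dr-dbt", "total", 14772, 36078, 465, 341, 124, 11)
  tb
}

# check every cell of the published tables against evaluate_workflow on a
# cohort (used for the fixture itself and after a CSV round trip)
expect_reproduces_tables <- function(cohort) {
  exp <- expected_cells()
  for (th in c(5, 7)) for (lo in c("sr-sm", "dr-sm")) for (hi in c("sr-dbt", "dr-dbt")) {
    res <- evaluate_workflow(cohort, lo, hi, threshold = th, ratio = 2,
                             reference_cancers = 135)
    want <- exp[exp$threshold == th & exp$low_arm == lo & exp$high_arm == hi, ]
    got <- res$summary[match(want$stratum, res$summary$stratum),
                       c("read_exams", "workload", "recalls", "fp_recalls",
                         "detected", "non_detected")]
    expect_equal(as.data.frame(got),
                 as.data.frame(want[names(got)]),
                 ignore_attr = TRUE,
                 label = sprintf("threshold %s, %s/%s", th, lo, hi))
  }
}
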