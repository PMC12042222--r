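test_that("arm_units implements the reading-time-equivalent model", {
  expect_equal(arm_units("sr-sm"), 1)
  expect_equal(arm_units("sr-sm", ratio = 1.7), 1)  # SM cost is the unit
  expect_equal(arm_units("dr-sm"), 2)
  expect_equal(arm_units("sr-dbt"), 2)
  expect_equal(arm_units("dr-dbt"), 4)
  expect_equal(arm_units("sr-dbt", ratio = 1.7), 1.7)
  expect_equal(arm_units("dr-dbt", ratio = 1.7), 3.4)
  expect_error(arm_units("dr-dm"), "reading arm")
})

test_that("conservation and additivity hold on random cohorts", {
  for (seed in 1:10) {
    co <- random_cohort(400, seed)
    th <- runif(1, 0, 10)
    res <- evaluate_workflow(co, "dr-sm", "sr-dbt", threshold = th)
    s <- res$summary
    expect_equal(s$recalls, s$fp_recalls + s$detected)
    tot <- s[s$stratum == "total", -1]
    expect_equal(as.numeric(tot),
                 as.numeric(s[s$stratum == "sm", -1]) +
                   as.numeric(s[s$stratum == "dbt", -1]))
    expect_equal(tot$detected + tot$non_detected, res$reference_cancers)
  }
})

test_that("thresholds 0 and above the maximum score reduce to uniform reading", {
  co <- random_cohort(500, 42)
  all_dbt <- evaluate_workflow(co, "sr-sm", "dr-dbt", threshold = 0)
  expect_equal(all_dbt$summary$read_exams[1], 0)        # SM stratum empty
  expect_equal(all_dbt$summary$recalls[3], sum(co$recall_dbt_dr))
  expect_equal(all_dbt$summary$workload[3], 4 * nrow(co))

  just_above <- min(10, max(co$ai_score) + 1e-9)
  all_sm <- evaluate_workflow(co, "dr-sm", "dr-dbt", threshold = just_above)
  expect_equal(all_sm$summary$read_exams[2], 0)         # DBT stratum empty
  expect_equal(all_sm$summary$recalls[3], sum(co$recall_sm_dr))
  expect_equal(all_sm$summary$workload[3], 2 * nrow(co))
})

test_that("validation rejects bad thresholds, arms and reference counts", {
  co <- random_cohort(100, 1)
  expect_error(evaluate_workflow(co, "sr-sm", "dr-dbt", threshold = 12),
               "\\[0, 10\\]")
  expect_error(evaluate_workflow(co, "sr-dbt", "dr-dbt", threshold = 5),
               "low_arm")
  expect_error(evaluate_workflow(co, "sr-sm", "dr-sm", threshold = 5),
               "high_arm")
  co$cancer[1] <- TRUE
  co$recall_dbt_dr[1] <- TRUE
  co <- as_cohort(co)
  expect_error(evaluate_workflow(co, "sr-sm", "dr-dbt", threshold = 0,
                                 reference_cancers = 0),
               "reference_cancers")
})

test_that("evaluate_workflow agrees with the per-record oracle", {
  for (seed in 1:8) {
    co <- random_cohort(sample(50:300, 1), seed)
    expect_matches_oracle(co, sample(c("sr-sm", "dr-sm"), 1),
                          sample(c("sr-dbt", "dr-dbt"), 1),
                          threshold = runif(1, 0, 10),
                          ratio = sample(c(1.7, 2), 1))
  }
})

test_that("threshold sweep matches pointwise evaluation and boundary shapes", {
  co <- random_cohort(600, 5)
  sw <- sweep_thresholds(co, grid = c(0, 2.5, 5, 7, 10))
  expect_equal(nrow(sw), 5 * 4)
  # spot-check one workflow against evaluate_workflow
  one <- sw[sw$low_arm == "sr-sm" & sw$high_arm == "dr-dbt" &
              sw$threshold == 5, ]
  res <- evaluate_workflow(co, "sr-sm", "dr-dbt", threshold = 5)
  tot <- res$summary[res$summary$stratum == "total", ]
  expect_equal(one$workload, tot$workload)
  expect_equal(one$detected, tot$detected)
  # flat curve when both arms cost two units
  flat <- sw[sw$low_arm == "dr-sm" & sw$high_arm == "sr-dbt", ]
  expect_true(all(flat$workload == 2 * nrow(co)))
  expect_error(sweep_thresholds(co, grid = c(5, 3)), "sorted")
})

test_that("workload is monotone non-increasing in threshold when DBT costs more", {
  co <- random_cohort(800, 9)
  sw <- sweep_thresholds(co, grid = seq(0, 10, by = 0.25))
  for (hi in c("sr-dbt", "dr-dbt")) {
    curve <- sw[sw$low_arm == "sr-sm" & sw$high_arm == hi, ]
    expect_true(all(diff(curve$workload) <= 0),
                label = paste("non-increasing workload, sr-sm /", hi))
  }
})

test_that("workload-neutral fraction has the stated closed forms", {
  expect_equal(workload_neutral_fraction("sr-sm", "dr-dbt"), 1 / 3)
  expect_equal(workload_neutral_fraction("sr-sm", "dr-dbt", ratio = 1.7),
               1 / 2.4)
  expect_true(is.na(workload_neutral_fraction("dr-sm", "sr-dbt")))
  # baseline below the cheaper arm is unattainable
  expect_true(is.na(workload_neutral_fraction("sr-sm", "dr-dbt",
                                              baseline_units_per_exam = 0.5)))
})

test_that("summaries round half-up and reject zero baselines", {
  expect_equal(round_half_up(16.5), 17)
  expect_equal(round_half_up(28.42), 28)
  expect_equal(round_half_up(-2.5), -3)
  expect_equal(round_half_up(8.2595, 2), 8.26)
  res <- evaluate_workflow(random_cohort(200, 2), "sr-sm", "dr-dbt",
                           threshold = 5)
  expect_error(summarize_vs_baseline(res, baseline_detected = 0), "positive")
})
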