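test_that("generated cohorts hit the cancer totals exactly and reproducibly", {
  p <- generator_params(n_exams = 2000, n_cancers_combined = 30,
                        n_cancers_sm_dr = 21, n_cancers_dbt_dr = 28)
  a <- generate_cohort(p, seed = 11)
  b <- generate_cohort(p, seed = 11)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_false(identical(as.data.frame(a),
                         as.data.frame(generate_cohort(p, seed = 12))))
  expect_equal(nrow(a), 2000)
  expect_equal(sum(a$cancer), 30)
  expect_equal(sum(a$cancer & a$recall_sm_dr), 21)
  expect_equal(sum(a$cancer & a$recall_dbt_dr), 28)
  # every reference cancer is detectable by at least one double-reading arm
  expect_true(all(a$recall_sm_dr[a$cancer] | a$recall_dbt_dr[a$cancer]))
})

test_that("single-reading recalls are nested inside double-reading recalls", {
  for (seed in 1:5) {
    co <- generate_cohort(generator_params(n_exams = 1000,
                                           n_cancers_combined = 12,
                                           n_cancers_sm_dr = 9,
                                           n_cancers_dbt_dr = 11), seed)
    expect_true(all(co$recall_sm_dr[co$recall_sm_sr]))
    expect_true(all(co$recall_dbt_dr[co$recall_dbt_sr]))
    expect_true(all(co$ai_score >= 0 & co$ai_score <= 10))
  }
})

test_that("a zero-cancer cohort makes every recall a false positive", {
  co <- generate_cohort(generator_params(n_exams = 500,
                                         n_cancers_combined = 0,
                                         n_cancers_sm_dr = 0,
                                         n_cancers_dbt_dr = 0), seed = 3)
  expect_equal(sum(co$cancer), 0)
  res <- evaluate_workflow(co, "sr-sm", "dr-dbt", threshold = 5)
  tot <- res$summary[res$summary$stratum == "total", ]
  expect_equal(tot$fp_recalls, tot$recalls)
  expect_equal(tot$detected, 0)
})

test_that("invalid generator parameters name the offending field", {
  expect_error(generator_params(n_exams = 0), "n_exams")
  expect_error(generator_params(n_cancers_sm_dr = 200), "n_cancers_sm_dr")
  # detected sets too small to cover the combined set
  expect_error(generator_params(n_cancers_combined = 135,
                                n_cancers_sm_dr = 50, n_cancers_dbt_dr = 60),
               "union")
  expect_error(generator_params(p_sr_given_dr = c(sm = 1.2, dbt = 0.9)),
               "p_sr_given_dr")
})

test_that("generate_cohort does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- .Random.seed
  invisible(generate_cohort(generator_params(n_exams = 100,
                                             n_cancers_combined = 2,
                                             n_cancers_sm_dr = 2,
                                             n_cancers_dbt_dr = 2), seed = 1))
  expect_identical(.Random.seed, before)
})

test_that("calibration matches tail targets analytically", {
  p <- calibrate_scores(calibration_targets(c(5, 7), c(0.30, 0.22)),
                        generator_params())
  tails <- screentriage:::mixture_tail(p, c(5, 7))
  expect_true(abs(tails[1] - 0.30) <= 0.005)
  expect_true(abs(tails[2] - 0.22) <= 0.005)
  # a different, feasible target set is also matched
  p2 <- calibrate_scores(calibration_targets(c(4, 8), c(0.40, 0.10)),
                         generator_params())
  expect_true(all(abs(screentriage:::mixture_tail(p2, c(4, 8)) -
                        c(0.40, 0.10)) <= 0.005))
})

test_that("degenerate and infeasible calibration targets behave as specified", {
  # P(score >= 0) = 1 holds for any distribution on [0, 10]
  p <- calibrate_scores(calibration_targets(0, 1.0), generator_params())
  expect_equal(screentriage:::mixture_tail(p, 0), 1)
  # tail fractions increasing in threshold are impossible
  expect_error(calibration_targets(c(5, 7), c(0.30, 0.35)), "non-increasing")
  expect_error(calibration_targets(c(5, 12), c(0.3, 0.2)), "\\[0, 10\\]")
})

test_that("cohort CSV round trip is lossless and schema errors are explicit", {
  co <- generate_cohort(generator_params(n_exams = 300,
                                         n_cancers_combined = 5,
                                         n_cancers_sm_dr = 4,
                                         n_cancers_dbt_dr = 4), seed = 7)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  back <- read_cohort(path)
  expect_equal(as.data.frame(back), as.data.frame(co), ignore_attr = TRUE)

  broken <- withr::local_tempfile(fileext = ".csv")
  tab <- utils::read.csv(path)
  readr::write_csv(tab[setdiff(names(tab), "recall_dbt_dr")], broken)
  expect_error(read_cohort(broken), "recall_dbt_dr")
})

test_that("cohort validation enforces the recall-nesting invariant", {
  bad <- tibble::tibble(exam_id = "x", ai_score = 3, cancer = FALSE,
                        recall_sm_sr = TRUE, recall_sm_dr = FALSE,
                        recall_dbt_sr = FALSE, recall_dbt_dr = FALSE)
  expect_error(as_cohort(bad), "recall_sm_sr")
  expect_error(as_cohort(tibble::tibble()), "missing required column")
})
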