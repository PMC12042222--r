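#' Generator parameters for synthetic screening cohorts
#'
#' Describes the stochastic model behind [generate_cohort()]. The defaults
#' are the study conditions the package emulates: 14,772 screened women with
#' 135 reference cancers (the cancers detectable by combined SM/DM and DBT
#' double reading), of which 95 are detected by SM double reading and 127 by
#' DBT double reading. Scores come from a three-component scaled-Beta
#' mixture (non-cancers; DBT-double-reading-detectable cancers; the
#' remaining, SM-only-detectable cancers); the default shapes are calibrated
#' so the mixture places 30\% of examinations at score >= 5 and 22\% at
#' score >= 7, and the DBT-detectable cancer component reproduces the
#' published fractions of those cancers above each threshold (116/127 at
#' >= 5, 112/127 at >= 7).
#'
#' Detectability is an exam-level property sampled exactly (without
#' replacement), so generated cohorts hit the three cancer totals exactly
#' rather than in expectation. Double-reading recall of a cancer equals its
#' detectability under that modality; false-positive double-reading recalls
#' of non-cancers are Bernoulli draws with piecewise-constant, score-band
#' dependent rates (`fp_breaks` delimit the bands). Single reading recalls a
#' case only if it was double-reading recalled AND the first reader flagged
#' it, modelled as an extra Bernoulli thinning with per-modality probability
#' `p_sr_given_dr`.
#'
#' @param n_exams Number of screened women.
#' @param n_cancers_combined Reference cancers (detectable by combined
#'   double reading of either modality).
#' @param n_cancers_sm_dr Cancers detected by SM/DM double reading.
#' @param n_cancers_dbt_dr Cancers detected by DBT double reading.
#' @param score_dist_noncancer,score_dist_cancer_dbt,score_dist_cancer_other
#'   [score_dist()] objects for the three mixture components.
#' @param p_sr_given_dr Named numeric, probabilities (per modality `sm`,
#'   `dbt`) that a double-reading recall is also a single-reading recall.
#' @param fp_rate Named list of per-band false-positive double-reading
#'   recall rates for `sm_dr` and `dbt_dr` (one rate per score band).
#' @param fp_breaks Increasing score cut points defining the bands.
#' @return An object of class `generator_params`.
#' @seealso [generate_cohort()], [calibrate_scores()]
#' @export
generator_params <- function(n_exams = 14772L,
                             n_cancers_combined = 135L,
                             n_cancers_sm_dr = 95L,
                             n_cancers_dbt_dr = 127L,
                             score_dist_noncancer =
                               score_dist(0.2134758, 0.4744288),
                             score_dist_cancer_dbt =
                               score_dist(0.5069065, 0.05423343),
                             score_dist_cancer_other =
                               score_dist(0.2797837, 0.09684465),
                             p_sr_given_dr = c(sm = 0.74, dbt = 0.90),
                             fp_rate = list(
                               sm_dr  = c(136, 29, 126) / c(10307, 1181, 3149),
                               dbt_dr = c(155, 35, 176) / c(10307, 1181, 3149)),
                             fp_breaks = c(5, 7)) {
  p <- list(n_exams = as.integer(n_exams),
            n_cancers_combined = as.integer(n_cancers_combined),
            n_cancers_sm_dr = as.integer(n_cancers_sm_dr),
            n_cancers_dbt_dr = as.integer(n_cancers_dbt_dr),
            score_dist_noncancer = score_dist_noncancer,
            score_dist_cancer_dbt = score_dist_cancer_dbt,
            score_dist_cancer_other = score_dist_cancer_other,
            p_sr_given_dr = p_sr_given_dr,
            fp_rate = fp_rate,
            fp_breaks = fp_breaks)
  class(p) <- "generator_params"
  validate_generator_params(p)
}

validate_generator_params <- function(p) {
  check <- function(ok, field, why) {
    if (!ok) stop(sprintf("invalid generator parameter '%s': %s", field, why),
                  call. = FALSE)
  }
  check(p$n_exams >= 1L, "n_exams", "must be a positive integer")
  check(p$n_cancers_combined >= 0L, "n_cancers_combined", "must be >= 0")
  check(p$n_cancers_combined <= p$n_exams, "n_cancers_combined",
        "cannot exceed n_exams")
  check(p$n_cancers_sm_dr >= 0L && p$n_cancers_sm_dr <= p$n_cancers_combined,
        "n_cancers_sm_dr", "must lie in [0, n_cancers_combined]")
  check(p$n_cancers_dbt_dr >= 0L && p$n_cancers_dbt_dr <= p$n_cancers_combined,
        "n_cancers_dbt_dr", "must lie in [0, n_cancers_combined]")
  check(p$n_cancers_sm_dr + p$n_cancers_dbt_dr >= p$n_cancers_combined,
        "n_cancers_sm_dr", paste("together with n_cancers_dbt_dr must cover",
                                 "n_cancers_combined (union constraint)"))
  for (f in c("score_dist_noncancer", "score_dist_cancer_dbt",
              "score_dist_cancer_other")) {
    check(inherits(p[[f]], "score_dist"), f, "must be a score_dist object")
  }
  check(all(c("sm", "dbt") %in% names(p$p_sr_given_dr)) &&
          all(p$p_sr_given_dr >= 0 & p$p_sr_given_dr <= 1),
        "p_sr_given_dr", "needs 'sm' and 'dbt' probabilities in [0, 1]")
  nb <- length(p$fp_breaks) + 1L
  check(!is.unsorted(p$fp_breaks, strictly = TRUE) &&
          all(p$fp_breaks > 0 & p$fp_breaks < 10),
        "fp_breaks", "must be strictly increasing within (0, 10)")
  for (arm in c("sm_dr", "dbt_dr")) {
    r <- p$fp_rate[[arm]]
    check(!is.null(r) && length(r) == nb && all(r >= 0 & r <= 1),
          "fp_rate", sprintf("component '%s' needs %d rates in [0, 1]", arm, nb))
  }
  invisible(p)
}

#' @export
print.generator_params <- function(x, ...) {
  cat(sprintf(paste0("<generator_params> %d exams, %d reference cancers ",
                     "(%d SM-DR, %d DBT-DR detected)\n"),
              x$n_exams, x$n_cancers_combined,
              x$n_cancers_sm_dr, x$n_cancers_dbt_dr))
  invisible(x)
}

band_index <- function(score, breaks) {
  findInterval(score, breaks, left.open = FALSE) + 1L
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic screening cohort
#'
#' Draws a cohort of `params$n_exams` examinations reproducibly from `seed`.
#' Cancer membership and the two detected sets are assigned by exact
#' sampling without replacement, so the totals `n_cancers_combined`,
#' `n_cancers_sm_dr` and `n_cancers_dbt_dr` are hit exactly in every
#' realisation; only scores, single-reader thinning and false-positive
#' recalls are random. All randomness flows through one stream seeded from
#' `seed`; the caller's RNG state is left untouched.
#'
#' @param params A [generator_params()] object.
#' @param seed Integer seed.
#' @return A validated cohort tibble (see [as_cohort()]).
#' @examples
#' co <- generate_cohort(generator_params(n_exams = 500, n_cancers_combined = 5,
#'                                        n_cancers_sm_dr = 4,
#'                                        n_cancers_dbt_dr = 4), seed = 1)
#' sum(co$cancer)
#' @export
generate_cohort <- function(params, seed) {
  validate_generator_params(params)
  stopifnot(is.numeric(seed), length(seed) == 1L)
  n <- params$n_exams
  with_seed(seed, {
    cancer <- logical(n)
    det_sm <- logical(n)
    det_dbt <- logical(n)
    nc <- params$n_cancers_combined
    if (nc > 0L) {
      idx <- sample.int(n, nc)
      cancer[idx] <- TRUE
      # partition the cancer set: SM-only / both / DBT-only, sizes fixed
      n_sm_only <- nc - params$n_cancers_dbt_dr
      n_both <- params$n_cancers_sm_dr + params$n_cancers_dbt_dr - nc
      shuffled <- sample(idx)
      sm_set <- shuffled[seq_len(n_sm_only + n_both)]
      dbt_set <- shuffled[(n_sm_only + 1L):nc]
      det_sm[sm_set] <- TRUE
      if (params$n_cancers_dbt_dr > 0L) det_dbt[dbt_set] <- TRUE
    }
    score <- numeric(n)
    score[!cancer] <- score_dist_sample(params$score_dist_noncancer,
                                        sum(!cancer))
    score[det_dbt] <- score_dist_sample(params$score_dist_cancer_dbt,
                                        sum(det_dbt))
    other <- cancer & !det_dbt
    score[other] <- score_dist_sample(params$score_dist_cancer_other,
                                      sum(other))
    band <- band_index(score, params$fp_breaks)
    fp_sm <- !cancer & stats::runif(n) < params$fp_rate$sm_dr[band]
    fp_dbt <- !cancer & stats::runif(n) < params$fp_rate$dbt_dr[band]
    recall_sm_dr <- det_sm | fp_sm
    recall_dbt_dr <- det_dbt | fp_dbt
    recall_sm_sr <- recall_sm_dr &
      stats::runif(n) < params$p_sr_given_dr[["sm"]]
    recall_dbt_sr <- recall_dbt_dr &
      stats::runif(n) < params$p_sr_given_dr[["dbt"]]
    as_cohort(
      tibble::tibble(
        exam_id = sprintf("exam-%06d", seq_len(n)),
        ai_score = score, cancer = cancer,
        recall_sm_sr = recall_sm_sr, recall_sm_dr = recall_sm_dr,
        recall_dbt_sr = recall_dbt_sr, recall_dbt_dr = recall_dbt_dr),
      provenance = sprintf("generated: n=%d cancers=%d/%d/%d seed=%d",
                           n, params$n_cancers_combined, params$n_cancers_sm_dr,
                           params$n_cancers_dbt_dr, as.integer(seed)))
  })
}

#' Calibration targets for the score mixture
#'
#' A set of tail constraints \eqn{P(\mathrm{score} \ge t_i) = f_i} that the
#' population score mixture must satisfy, e.g. the published stratum
#' fractions: 30\% of examinations at score >= 5 and 22\% at >= 7.
#'
#' @param thresholds Numeric thresholds in \eqn{[0, 10]}.
#' @param fractions Target population fractions in \eqn{[0, 1]};
#'   must be non-increasing in threshold.
#' @return An object of class `calibration_targets`.
#' @export
calibration_targets <- function(thresholds = c(5, 7),
                                fractions = c(0.30, 0.22)) {
  stopifnot(length(thresholds) == length(fractions), length(thresholds) >= 1L)
  if (any(thresholds < 0 | thresholds > 10)) {
    stop("calibration thresholds must lie in [0, 10]", call. = FALSE)
  }
  if (any(fractions < 0 | fractions > 1)) {
    stop("calibration fractions must lie in [0, 1]", call. = FALSE)
  }
  ord <- order(thresholds)
  if (is.unsorted(rev(fractions[ord]))) {
    stop("infeasible calibration targets: tail fractions must be ",
         "non-increasing in threshold", call. = FALSE)
  }
  structure(list(thresholds = thresholds[ord], fractions = fractions[ord]),
            class = "calibration_targets")
}

mixture_tail <- function(params, q) {
  n <- params$n_exams
  w_dbt <- params$n_cancers_dbt_dr / n
  w_oth <- (params$n_cancers_combined - params$n_cancers_dbt_dr) / n
  w_nc <- 1 - w_dbt - w_oth
  w_nc * score_dist_tail(params$score_dist_noncancer, q) +
    w_dbt * score_dist_tail(params$score_dist_cancer_dbt, q) +
    w_oth * score_dist_tail(params$score_dist_cancer_other, q)
}

#' Calibrate the non-cancer score distribution to tail constraints
#'
#' Refits the non-cancer Beta component of `params` so that the full score
#' mixture (non-cancer + the two fixed cancer components, weighted by the
#' cancer totals) satisfies each tail constraint in `targets`. The fit is
#' analytic on the mixture CDF — no sampling — by Nelder-Mead least squares
#' over the log shape parameters. If the worst residual exceeds `tol` the
#' calibration fails with a diagnostic.
#'
#' @param targets A [calibration_targets()] object.
#' @param params A [generator_params()] object; only its non-cancer
#'   component is refitted.
#' @param tol Maximum absolute error allowed on any target fraction.
#' @return `params` with a recalibrated `score_dist_noncancer`.
#' @examples
#' p <- calibrate_scores(calibration_targets(c(5, 7), c(0.30, 0.22)),
#'                       generator_params())
#' @export
calibrate_scores <- function(targets, params, tol = 0.005) {
  stopifnot(inherits(targets, "calibration_targets"))
  validate_generator_params(params)
  objective <- function(theta) {
    cand <- params
    cand$score_dist_noncancer <- score_dist(exp(theta[1]), exp(theta[2]))
    sum((mixture_tail(cand, targets$thresholds) - targets$fractions)^2)
  }
  start <- log(c(params$score_dist_noncancer$shape1,
                 params$score_dist_noncancer$shape2))
  fit <- stats::optim(start, objective, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
  out <- params
  out$score_dist_noncancer <- score_dist(exp(fit$par[1]), exp(fit$par[2]))
  resid <- mixture_tail(out, targets$thresholds) - targets$fractions
  worst <- which.max(abs(resid))
  if (abs(resid[worst]) > tol) {
    stop(sprintf(paste0("calibration failed: worst residual %.4f at ",
                        "threshold %.2f (target %.3f, tolerance %.3f)"),
                 resid[worst], targets$thresholds[worst],
                 targets$fractions[worst], tol), call. = FALSE)
  }
  out
}
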