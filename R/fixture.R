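# Band-level targets obtained by differencing the published threshold-5 and
# threshold-7 stratum tables. Three score bands: below 5, 5 to <7, 7 and up.
# Cells the two tables do not pin down (SM arms in the top band; DBT arms in
# the bottom band beyond the global 127 DBT-DR total) are fixed, plausible
# values chosen once; thresholds 5 and 7 are insensitive to them row-wise
# only where the tables constrain them.
fixture_band_targets <- function() {
  list(
    size    = c(10320L, 1185L, 3267L),
    score   = c(2.5, 6.0, 8.5),          # any value inside the band works
    cancers = c(13L, 4L, 118L),
    # detected cancers: index windows [lo, hi] within each band's cancer list;
    # windows are chosen so SM-DR and DBT-DR jointly cover every cancer
    det = list(
      sm_dr  = list(c(1L, 9L),  c(1L, 3L), c(1L, 83L)),
      sm_sr  = list(c(1L, 6L),  c(1L, 2L), c(1L, 74L)),
      dbt_dr = list(c(3L, 13L), c(1L, 4L), c(7L, 118L)),
      dbt_sr = list(c(3L, 10L), c(1L, 4L), c(7L, 107L))),
    # false-positive recalls: counts of non-cancers per band (prefix sets,
    # single-reader recalls nested inside double-reader recalls)
    fp = list(
      sm_dr  = c(136L, 29L, 126L),
      sm_sr  = c(101L, 22L, 95L),
      dbt_dr = c(155L, 35L, 176L),
      dbt_sr = c(120L, 25L, 151L))
  )
}

check_fixture_targets <- function(t) {
  fail <- function(msg) stop("fixture band targets are inconsistent: ", msg,
                             call. = FALSE)
  if (length(t$size) != 3L || any(t$size <= t$cancers)) {
    fail("band sizes must exceed band cancer counts")
  }
  width <- function(w) w[2] - w[1] + 1L
  for (b in 1:3) {
    if (t$score[b] < c(0, 5, 7)[b] || t$score[b] >= c(5, 7, 10)[b]) {
      fail(sprintf("representative score for band %d outside its interval", b))
    }
    for (arm in names(t$det)) {
      w <- t$det[[arm]][[b]]
      if (w[1] < 1L || w[2] > t$cancers[b] || w[1] > w[2] + 1L) {
        fail(sprintf("detected window for %s in band %d out of range", arm, b))
      }
    }
    for (mod in c("sm", "dbt")) {
      sr <- t$det[[paste0(mod, "_sr")]][[b]]
      dr <- t$det[[paste0(mod, "_dr")]][[b]]
      if (sr[1] < dr[1] || sr[2] > dr[2]) {
        fail(sprintf("%s single-reader detected set not nested in band %d",
                     mod, b))
      }
      if (t$fp[[paste0(mod, "_sr")]][b] > t$fp[[paste0(mod, "_dr")]][b]) {
        fail(sprintf("%s single-reader FP count exceeds double-reader in band %d",
                     mod, b))
      }
      if (t$fp[[paste0(mod, "_dr")]][b] > t$size[b] - t$cancers[b]) {
        fail(sprintf("%s FP count exceeds non-cancers in band %d", mod, b))
      }
    }
    # combined double reading must detect every reference cancer in the band
    sm <- t$det$sm_dr[[b]]; dbt <- t$det$dbt_dr[[b]]
    covered <- union(seq.int(sm[1], sm[2]), seq.int(dbt[1], dbt[2]))
    if (!setequal(covered, seq_len(t$cancers[b]))) {
      fail(sprintf("SM-DR and DBT-DR do not jointly cover band %d cancers", b))
    }
  }
  invisible(t)
}

#' Deterministic fixture cohort reproducing the published worked examples
#'
#' Constructs, with no randomness, a cohort of 14,772 examinations and 135
#' reference cancers whose evaluation under every one of the four
#' single/double-reading workflow combinations at thresholds 5 and 7
#' reproduces cell-for-cell the published per-stratum tables (read
#' examinations, workload at ratio 2, recalls, false-positive recalls,
#' detected and non-detected cancers), as well as the global totals of 95
#' SM-double-reading-detected and 127 DBT-double-reading-detected cancers.
#'
#' The construction assigns integer counts over three score bands (score
#' below 5, 5 to below 7, 7 and above, with fixed representative scores 2.5,
#' 6.0 and 8.5) whose band-level targets are obtained by differencing the
#' two published threshold tables. Single-reader recalled sets are nested
#' inside double-reader recalled sets, and the SM-DR and DBT-DR detected
#' sets jointly cover every reference cancer. An internal consistency check
#' of the band targets runs first and aborts with a diagnostic if they are
#' ever edited into infeasibility.
#'
#' @return A validated cohort tibble (see [as_cohort()]) with provenance
#'   `"fixture"`.
#' @examples
#' fx <- build_fixture_cohort()
#' evaluate_workflow(fx, "sr-sm", "dr-dbt", threshold = 5)
#' @export
build_fixture_cohort <- function() {
  t <- check_fixture_targets(fixture_band_targets())
  bands <- lapply(1:3, function(b) {
    n <- t$size[b]
    ncan <- t$cancers[b]
    cancer <- c(rep(TRUE, ncan), rep(FALSE, n - ncan))
    flag <- function(arm) {
      w <- t$det[[arm]][[b]]
      det <- seq_len(ncan) >= w[1] & seq_len(ncan) <= w[2]
      fp <- seq_len(n - ncan) <= t$fp[[arm]][b]
      c(det, fp)
    }
    tibble::tibble(
      ai_score = rep(t$score[b], n),
      cancer = cancer,
      recall_sm_sr = flag("sm_sr"), recall_sm_dr = flag("sm_dr"),
      recall_dbt_sr = flag("dbt_sr"), recall_dbt_dr = flag("dbt_dr"))
  })
  out <- do.call(rbind, bands)
  out <- tibble::add_column(out,
                            exam_id = sprintf("fx-%05d", seq_len(nrow(out))),
                            .before = 1L)
  as_cohort(out, provenance = "fixture")
}
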