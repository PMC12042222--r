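COHORT_COLUMNS <- c("exam_id", "ai_score", "cancer",
                    "recall_sm_sr", "recall_sm_dr",
                    "recall_dbt_sr", "recall_dbt_dr")

#' Screening cohort tables
#'
#' A cohort is a tibble with one row per screened woman and columns
#' `exam_id` (unique identifier), `ai_score` (continuous, 0--10), `cancer`
#' (logical: member of the reference cancer set, i.e. the cancers detectable
#' by combined SM/DM and DBT double reading), and four per-arm final recall
#' outcomes `recall_sm_sr`, `recall_sm_dr`, `recall_dbt_sr`,
#' `recall_dbt_dr`. Single reading recalls a case only when the first
#' reader's flag is among those confirmed at the consensus meeting, so
#' single-reading recall implies double-reading recall for the same
#' modality; `validate_cohort()` enforces this nesting together with the
#' score range and identifier uniqueness. A `provenance` attribute records
#' how the table was made (generator parameters and seed, `"fixture"`, or a
#' file path).
#'
#' @param x A data frame with the columns above.
#' @param provenance Free-text provenance tag.
#' @return `as_cohort()` and `validate_cohort()` return the validated cohort
#'   (a tibble with class `screening_cohort`).
#' @seealso [generate_cohort()], [build_fixture_cohort()], [read_cohort()]
#' @export
as_cohort <- function(x, provenance = "unspecified") {
  x <- tibble::as_tibble(x)
  missing <- setdiff(COHORT_COLUMNS, names(x))
  if (length(missing)) {
    stop("cohort is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  x <- x[COHORT_COLUMNS]
  for (col in COHORT_COLUMNS[3:7]) x[[col]] <- as.logical(x[[col]])
  x$ai_score <- as.double(x$ai_score)
  class(x) <- c("screening_cohort", class(x))
  attr(x, "provenance") <- provenance
  validate_cohort(x)
}

#' @rdname as_cohort
#' @export
validate_cohort <- function(x) {
  stopifnot(is.data.frame(x))
  if (nrow(x) == 0L) stop("cohort must be non-empty", call. = FALSE)
  if (anyDuplicated(x$exam_id)) {
    stop("exam_id values must be unique", call. = FALSE)
  }
  if (anyNA(x$ai_score) || any(x$ai_score < 0 | x$ai_score > 10)) {
    stop("ai_score must lie in [0, 10] with no missing values", call. = FALSE)
  }
  flags <- as.matrix(x[COHORT_COLUMNS[3:7]])
  if (anyNA(flags)) stop("recall/cancer flags must not be missing", call. = FALSE)
  if (any(x$recall_sm_sr & !x$recall_sm_dr)) {
    stop("recall_sm_sr must imply recall_sm_dr (consensus nesting)", call. = FALSE)
  }
  if (any(x$recall_dbt_sr & !x$recall_dbt_dr)) {
    stop("recall_dbt_sr must imply recall_dbt_dr (consensus nesting)", call. = FALSE)
  }
  invisible(x)
}

#' @export
print.screening_cohort <- function(x, ...) {
  cat(sprintf(
    "<screening_cohort> %d examinations, %d reference cancers (provenance: %s)\n",
    nrow(x), sum(x$cancer), attr(x, "provenance") %||% "unspecified"))
  NextMethod()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read and write cohort CSV files
#'
#' The on-disk format is a plain comma-separated file with a header row and
#' the seven cohort columns; logical flags are serialised as 0/1 and scores
#' as full-precision decimals, so a write/read round trip is lossless.
#'
#' @param cohort A cohort table (see [as_cohort()]).
#' @param path File path.
#' @return `read_cohort()` returns a validated cohort; `write_cohort()`
#'   returns `path` invisibly.
#' @examples
#' \donttest{
#' p <- tempfile(fileext = ".csv")
#' write_cohort(build_fixture_cohort(), p)
#' nrow(read_cohort(p))
#' }
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  out <- as.data.frame(cohort)[COHORT_COLUMNS]
  for (col in COHORT_COLUMNS[3:7]) out[[col]] <- as.integer(out[[col]])
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_guess()))
  missing <- setdiff(COHORT_COLUMNS, names(raw))
  if (length(missing)) {
    stop("cohort CSV is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  prob <- readr::problems(raw)
  if (nrow(prob)) {
    stop(sprintf("malformed cohort CSV: %d parsing problem(s), first at line %d",
                 nrow(prob), prob$row[1]), call. = FALSE)
  }
  for (col in COHORT_COLUMNS[3:7]) {
    v <- raw[[col]]
    if (is.numeric(v) && !all(v %in% c(0, 1))) {
      stop("column ", col, " must contain only 0/1 values", call. = FALSE)
    }
  }
  as_cohort(raw, provenance = paste0("read:", path))
}
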