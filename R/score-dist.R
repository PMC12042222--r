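#' Scaled Beta score distribution
#'
#' A parametric distribution on the AI-score range \eqn{[0, 10]}: a Beta
#' distribution with shape parameters `shape1` and `shape2`, scaled from
#' \eqn{[0, 1]} to \eqn{[0, 10]}. Bounded support matches the score an
#' examination-level cancer-detection system assigns, and the two shapes are
#' enough freedom to hit two tail-probability constraints, which is all the
#' published stratum fractions provide.
#'
#' @param shape1,shape2 Positive Beta shape parameters.
#' @return An object of class `score_dist`.
#' @examples
#' d <- score_dist(2, 5)
#' score_dist_tail(d, 5) # P(score >= 5)
#' @export
score_dist <- function(shape1, shape2) {
  stopifnot(is.numeric(shape1), length(shape1) == 1L, shape1 > 0,
            is.numeric(shape2), length(shape2) == 1L, shape2 > 0)
  structure(list(shape1 = shape1, shape2 = shape2, lower = 0, upper = 10),
            class = "score_dist")
}

#' @export
print.score_dist <- function(x, ...) {
  cat(sprintf("<score_dist> Beta(%.4g, %.4g) scaled to [0, 10]\n",
              x$shape1, x$shape2))
  invisible(x)
}

#' @rdname score_dist
#' @param d A `score_dist`.
#' @param q Score value(s) in \eqn{[0, 10]}.
#' @return `score_dist_cdf()`: \eqn{P(X \le q)}; `score_dist_tail()`:
#'   \eqn{P(X \ge q)} (the two coincide in complement because the
#'   distribution is continuous).
#' @export
score_dist_cdf <- function(d, q) {
  stopifnot(inherits(d, "score_dist"))
  stats::pbeta((q - d$lower) / (d$upper - d$lower), d$shape1, d$shape2)
}

#' @rdname score_dist
#' @export
score_dist_tail <- function(d, q) 1 - score_dist_cdf(d, q)

#' @rdname score_dist
#' @param n Number of draws.
#' @export
score_dist_sample <- function(d, n) {
  stopifnot(inherits(d, "score_dist"))
  d$lower + (d$upper - d$lower) * stats::rbeta(n, d$shape1, d$shape2)
}
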