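#' Log hazard ratio from a log-rank p-value and event count
#'
#' Indirect reconstruction for trials that publish a two-sided log-rank
#' p-value and total event count but no hazard ratio.  Under the usual
#' approximation the log-rank variance is
#' `V = events * R / (1 + R)^2` with allocation ratio `R`; the observed
#' minus expected events is `O - E = sign * z * sqrt(V)` with
#' `z` the normal quantile at `p/2`, giving `log HR = (O - E) / V` and
#' `se = 1 / sqrt(V)`.
#'
#' @param events_total total number of events across both arms.
#' @param p_two_sided two-sided log-rank p-value, strictly in (0, 1).
#' @param allocation_ratio patients in arm 1 / patients in arm 2.
#' @param favors_trt direction of effect: `TRUE` when the point estimate
#'   favors the treatment arm (log HR < 0).
#' @return List with `y` (log HR) and `se`.
#' @export
#' @examples
#' hr_from_logrank(100, 0.05, 1)
hr_from_logrank <- function(events_total, p_two_sided,
                            allocation_ratio = 1, favors_trt = TRUE) {
  if (events_total <= 0) stop("events_total must be positive")
  if (p_two_sided <= 0 || p_two_sided >= 1)
    stop("p-value must lie strictly in (0, 1)")
  R <- allocation_ratio
  V <- events_total * R / (1 + R)^2
  z <- stats::qnorm(p_two_sided / 2, lower.tail = FALSE)
  ome <- (if (favors_trt) -1 else 1) * z * sqrt(V)
  list(y = ome / V, se = 1 / sqrt(V))
}

#' Point hazard ratio from two median survival times
#'
#' Under exponential survival the hazard is `log(2) / median`, so the
#' hazard ratio of treatment versus control is the inverse ratio of the
#' medians.  No standard error is recoverable from the medians alone:
#' the result is a point estimate and is never fed to the likelihood
#' unless the caller attaches an `se`.
#'
#' @param median_trt,median_ctrl median survival times (months), > 0.
#' @return The point hazard ratio (treatment vs control).
#' @export
#' @examples
#' hr_from_medians(5.1, 2.2)   # nivolumab vs dacarbazine: ~0.43
hr_from_medians <- function(median_trt, median_ctrl) {
  if (any(c(median_trt, median_ctrl) <= 0)) stop("medians must be positive")
  median_ctrl / median_trt
}

#' Log odds ratio from a 2x2 table of adverse-event counts
#'
#' @param events1,n1 events and size of arm 1.
#' @param events2,n2 events and size of arm 2.
#' @param correction continuity constant added to all four cells when
#'   any cell is zero (Haldane–Anscombe; default 0.5).  `correction = 0`
#'   rejects degenerate tables instead.
#' @return List with `y` (log OR of arm 1 vs arm 2) and `se`
#'   (`sqrt(1/a + 1/b + 1/c + 1/d)` on the possibly corrected cells).
#' @export
or_from_counts <- function(events1, n1, events2, n2, correction = 0.5) {
  if (any(c(events1, events2) < 0) || events1 > n1 || events2 > n2 ||
        any(c(n1, n2) <= 0))
    stop("invalid 2x2 table")
  a <- events1; b <- n1 - events1; c <- events2; d <- n2 - events2
  if (min(a, b, c, d) == 0) {
    if (correction <= 0)
      stop("zero cell with no continuity correction")
    a <- a + correction; b <- b + correction
    c <- c + correction; d <- d + correction
  }
  list(y = log(a * d / (b * c)),
       se = sqrt(1 / a + 1 / b + 1 / c + 1 / d))
}
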