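#' Gelman-Rubin potential scale reduction factor
#'
#' `PSRF = sqrt(((n-1)/n * W + B/n) / W)` per parameter, with `W` the
#' mean within-chain variance and `B` the between-chain variance
#' (`n * var` of the chain means).  Constant identical chains (`W = 0`)
#' are reported as 1 by convention.
#'
#' @param chains list (length >= 2) of equal-sized draw matrices with
#'   identical column names, one per chain.
#' @return Named vector of PSRF values, one per column.
#' @export
gelman_rubin <- function(chains) {
  if (length(chains) < 2) stop("PSRF needs at least 2 chains")
  n <- unique(vapply(chains, nrow, 1L))
  if (length(n) != 1L) stop("chains must have equal retained lengths")
  pars <- colnames(chains[[1L]])
  vapply(pars, function(p) {
    x <- vapply(chains, function(m) m[, p], numeric(n))
    W <- mean(apply(x, 2, stats::var))
    B <- n * stats::var(colMeans(x))
    if (W == 0) return(1)
    sqrt(((n - 1) / n * W + B / n) / W)
  }, numeric(1))
}

#' Comparison-adjusted funnel-plot points
#'
#' Centers every contrast on the fixed-effect direct pooled estimate of
#' its own comparison, so that trials from different comparisons share a
#' common zero and one funnel can display the whole network.  Points of
#' single-study comparisons sit exactly at zero.
#'
#' @param network an `evidence_network`.
#' @param outcome outcome label.
#' @param directs optional data.frame from [pairwise_all()]; computed
#'   from `network` when missing.
#' @return data.frame with columns `trial_id`, `baseline`, `treatment`,
#'   `comparison`, `y`, `pooled`, `centered`, `se`.
#' @export
funnel_points <- function(network, outcome = "PFS", directs = NULL) {
  ct <- network$contrasts[network$contrasts$outcome == outcome, ,
                          drop = FALSE]
  if (!nrow(ct)) stop("no contrasts for outcome ", outcome)
  if (is.null(directs)) directs <- pairwise_all(network, outcome)
  d <- directs[directs$method == "fixed_iv", , drop = FALSE]
  key <- paste(ct$baseline, ct$treatment, sep = " vs ")
  dkey <- paste(d$baseline, d$treatment, sep = " vs ")
  pooled <- d$estimate[match(key, dkey)]
  if (anyNA(pooled))
    stop("no direct pooled estimate for: ",
         paste(unique(key[is.na(pooled)]), collapse = ", "))
  data.frame(trial_id = ct$trial_id, baseline = ct$baseline,
             treatment = ct$treatment, comparison = key,
             y = ct$y, pooled = pooled, centered = ct$y - pooled,
             se = ct$se, stringsAsFactors = FALSE)
}

#' Funnel plot of centered effects against standard error
#' @param fp data.frame from [funnel_points()].
#' @param ... passed to [graphics::plot.default()].
#' @export
plot_funnel <- function(fp, ...) {
  graphics::plot(fp$centered, fp$se, ylim = rev(range(c(0, fp$se))),
                 xlab = "log effect centered on comparison pool",
                 ylab = "standard error", pch = 19, ...)
  z <- stats::qnorm(0.975)
  s <- seq(0, max(fp$se) * 1.05, length.out = 50)
  graphics::lines(-z * s, s, lty = 2)
  graphics::lines(z * s, s, lty = 2)
  graphics::abline(v = 0, lty = 3)
  invisible(fp)
}
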