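#' Fixed-effect inverse-variance pooling
#'
#' @param y log effects.
#' @param se standard errors (> 0), same length as `y`.
#' @param level CI coverage.
#' @return Object of class `pairwise_result`: pooled log effect, `se`,
#'   CI, heterogeneity statistics (for >= 2 studies) and `method`.
#' @export
pool_fixed <- function(y, se, level = 0.95) {
  if (!length(y)) stop("no effects to pool")
  if (length(y) != length(se) || any(se <= 0)) stop("invalid standard errors")
  w <- 1 / se^2
  est <- sum(w * y) / sum(w)
  pse <- 1 / sqrt(sum(w))
  z <- stats::qnorm((1 + level) / 2)
  het <- if (length(y) >= 2) heterogeneity(y, se) else
    list(Q = 0, df = 0, p_Q = NA_real_, I2 = 0, tau2_DL = 0,
         severe = FALSE)
  structure(c(list(method = "fixed_iv", estimate = est, se = pse,
                   lower = est - z * pse, upper = est + z * pse,
                   n_studies = length(y)), het),
            class = "pairwise_result")
}

#' Cochran's Q, I-squared and the DerSimonian-Laird variance
#'
#' `Q = sum w (y - pooled)^2` about the fixed-effect pool with
#' `w = 1/se^2`; `I2 = max(0, (Q - df)/Q) * 100`;
#' `tau2_DL = max(0, (Q - df) / (sum w - sum w^2 / sum w))`.  Severe
#' heterogeneity is flagged when `I2 > 50` or `p_Q < 0.10`.
#'
#' @inheritParams pool_fixed
#' @return List with `Q`, `df`, `p_Q`, `I2`, `tau2_DL`, `severe`.
#' @export
heterogeneity <- function(y, se) {
  if (length(y) < 2) stop("heterogeneity needs at least 2 effects")
  w <- 1 / se^2
  est <- sum(w * y) / sum(w)
  Q <- sum(w * (y - est)^2)
  df <- length(y) - 1
  p_Q <- stats::pchisq(Q, df, lower.tail = FALSE)
  I2 <- if (Q > 0) max(0, (Q - df) / Q) * 100 else 0
  tau2 <- max(0, (Q - df) / (sum(w) - sum(w^2) / sum(w)))
  list(Q = Q, df = df, p_Q = p_Q, I2 = I2, tau2_DL = tau2,
       severe = I2 > 50 || (!is.na(p_Q) && p_Q < 0.10))
}

#' DerSimonian-Laird random-effects pooling
#'
#' Inverse-variance pooling with weights `1/(se^2 + tau2_DL)`.
#' Reduces to [pool_fixed()] when the moment estimate of the
#' between-trial variance is zero.
#'
#' @inheritParams pool_fixed
#' @return A `pairwise_result` with `method = "random_dl"`.
#' @export
pool_random <- function(y, se, level = 0.95) {
  if (length(y) < 2) stop("random-effects pooling needs >= 2 effects")
  het <- heterogeneity(y, se)
  w <- 1 / (se^2 + het$tau2_DL)
  est <- sum(w * y) / sum(w)
  pse <- 1 / sqrt(sum(w))
  z <- stats::qnorm((1 + level) / 2)
  structure(c(list(method = "random_dl", estimate = est, se = pse,
                   lower = est - z * pse, upper = est + z * pse,
                   n_studies = length(y)), het),
            class = "pairwise_result")
}

#' @export
print.pairwise_result <- function(x, ...) {
  cat(x$method, ": pooled ratio ",
      sprintf("%.3f (%.3f-%.3f)", exp(x$estimate), exp(x$lower),
              exp(x$upper)),
      " from ", x$n_studies, " studies\n", sep = "")
  if (x$n_studies >= 2)
    cat(sprintf("Q = %.3f (df %d, p = %.3f), I2 = %.1f%%, tau2 = %.4f%s\n",
                x$Q, x$df, x$p_Q, x$I2, x$tau2_DL,
                if (x$severe) " [severe heterogeneity]" else ""))
  invisible(x)
}

#' Traditional pairwise meta-analysis of every direct comparison
#'
#' Groups a network's contrasts by (baseline, treatment, outcome) —
#' multi-arm trials contribute each pair once via their baseline-
#' anchored contrast — and pools each group by both fixed- and
#' random-effects methods (random requires >= 2 studies).
#'
#' @param network an `evidence_network`.
#' @param outcome outcome label.
#' @return data.frame with one row per comparison and method: columns
#'   `baseline`, `treatment`, `method`, `n_studies`, `estimate`, `se`,
#'   `lower`, `upper`, `Q`, `df`, `p_Q`, `I2`, `tau2_DL`, `severe`.
#' @export
pairwise_all <- function(network, outcome = "PFS") {
  ct <- network$contrasts[network$contrasts$outcome == outcome, ,
                          drop = FALSE]
  if (!nrow(ct)) stop("no contrasts for outcome ", outcome)
  key <- paste(ct$baseline, ct$treatment, sep = " vs ")
  rows <- list()
  for (k in unique(key)) {
    idx <- which(key == k)
    fits <- list(pool_fixed(ct$y[idx], ct$se[idx]))
    if (length(idx) >= 2)
      fits <- c(fits, list(pool_random(ct$y[idx], ct$se[idx])))
    for (f in fits)
      rows[[length(rows) + 1L]] <- data.frame(
        baseline = ct$baseline[idx[1L]], treatment = ct$treatment[idx[1L]],
        method = f$method, n_studies = f$n_studies, estimate = f$estimate,
        se = f$se, lower = f$lower, upper = f$upper, Q = f$Q, df = f$df,
        p_Q = f$p_Q, I2 = f$I2, tau2_DL = f$tau2_DL, severe = f$severe,
        stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Direct-versus-network consistency table
#'
#' Pairs every direct (pairwise) pooled estimate with the corresponding
#' network (league-table) estimate, flags whether the two intervals
#' overlap and records the log-scale difference.  Non-overlap signals
#' potential inconsistency between direct and indirect evidence.
#'
#' @param lt a [league_table()] (build it with the auxiliary node
#'   included via `include` if directs involve it).
#' @param directs data.frame from [pairwise_all()]; the fixed-effect
#'   rows are used unless `method = "random_dl"`.
#' @param method which pairwise method to compare against.
#' @return data.frame with columns `baseline`, `treatment`,
#'   `direct`, `direct_lower`, `direct_upper`, `network`,
#'   `network_lower`, `network_upper`, `log_diff`, `overlap`.
#' @export
consistency_table <- function(lt, directs, method = "fixed_iv") {
  d <- directs[directs$method == method, , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(d))) {
    b <- d$baseline[i]; t <- d$treatment[i]
    if (!(b %in% rownames(lt$median)) || !(t %in% colnames(lt$median)))
      stop("comparison ", t, " vs ", b, " absent from the league table")
    net <- league_entry(lt, col = t, row = b)
    dir <- exp(c(d$estimate[i], d$lower[i], d$upper[i]))
    rows[[i]] <- data.frame(
      baseline = b, treatment = t,
      direct = dir[1], direct_lower = dir[2], direct_upper = dir[3],
      network = net[["median"]], network_lower = net[["lower"]],
      network_upper = net[["upper"]],
      log_diff = log(dir[1]) - log(net[["median"]]),
      overlap = dir[2] <= net[["upper"]] && net[["lower"]] <= dir[3],
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
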