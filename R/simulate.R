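#' Specify the truth of a synthetic evidence network
#'
#' Defines treatments, true basic parameters (log scale, versus the
#' first treatment as reference), between-trial heterogeneity and a
#' trial layout from which [simulate_contrast_network()] and
#' [simulate_ae_network()] draw reproducible data.  The default layout
#' mirrors the melanoma evidence geometry: a chemotherapy hub with
#' two-arm spokes, an ipilimumab hub, and one three-arm trial closing a
#' loop.
#'
#' @param treatments character vector; the first is the reference.
#' @param d_true named log effects versus the reference for every
#'   non-reference treatment.
#' @param tau_true between-trial standard deviation (>= 0).
#' @param layout list of trials, each a list with `baseline`,
#'   `comparators` (character vector), and either `se` (per-contrast
#'   standard errors, contrast model) and optionally `n` (per-arm
#'   enrolment, baseline first), or `n` alone for arm-level binomial
#'   simulation.
#' @param baseline_logodds,baseline_sd mean and sd of the normal
#'   distribution of trial baseline log odds (binomial simulation).
#' @param outcome outcome label stamped on simulated contrasts
#'   (`"AE_high"` data are written to the arm counts instead).
#' @param seed integer seed making the simulation deterministic.
#' @return Object of class `sim_truth`.
#' @export
sim_truth <- function(treatments = c("CHE", "IPI", "TRE", "NIV", "PEM",
                                     "IPI_NIV"),
                      d_true = c(IPI = -0.1, TRE = -0.45, NIV = -0.75,
                                 PEM = -0.65, IPI_NIV = -0.95),
                      tau_true = 0,
                      layout = NULL,
                      baseline_logodds = -1, baseline_sd = 0.5,
                      outcome = "PFS", seed = 1L) {
  if (is.null(layout))
    layout <- list(
      list(baseline = "CHE", comparators = "TRE", se = 0.17, n = c(330, 330)),
      list(baseline = "CHE", comparators = "NIV", se = 0.13, n = c(210, 210)),
      list(baseline = "CHE", comparators = "PEM", se = 0.12, n = c(180, 360)),
      list(baseline = "IPI", comparators = c("NIV", "IPI_NIV"),
           se = c(0.15, 0.16), n = c(315, 316, 314)),
      list(baseline = "IPI", comparators = "IPI_NIV", se = 0.28,
           n = c(47, 95)),
      list(baseline = "IPI", comparators = "PEM", se = 0.11, n = c(278, 556)))
  miss <- setdiff(treatments[-1L], names(d_true))
  if (length(miss))
    stop("d_true missing for: ", paste(miss, collapse = ", "))
  if (tau_true < 0) stop("tau_true must be >= 0")
  # the layout's comparison graph must span and connect all treatments
  comp <- stats::setNames(seq_along(treatments), treatments)
  for (tr in layout) for (k in tr$comparators) {
    m <- min(comp[tr$baseline], comp[k])
    comp[comp %in% comp[c(tr$baseline, k)]] <- m
  }
  if (length(unique(comp)) > 1L)
    stop("layout comparison graph disconnected: ",
         paste(tapply(names(comp), comp, paste, collapse = "+"),
               collapse = " | "))
  structure(list(treatments = treatments, d_true = d_true,
                 tau_true = tau_true, layout = layout,
                 baseline_logodds = baseline_logodds,
                 baseline_sd = baseline_sd,
                 outcome = outcome, seed = as.integer(seed)),
            class = "sim_truth")
}

sim_treatment_frame <- function(treatments) {
  data.frame(id = treatments, label = treatments,
             reportable = TRUE, stringsAsFactors = FALSE)
}

sim_dcon <- function(truth, trt, base) {
  dv <- function(t) if (t == truth$treatments[1L]) 0 else truth$d_true[[t]]
  vapply(trt, dv, 0) - dv(base)
}

# trial effects with the 0.5 tau^2 within-trial correlation, drawn by
# the sequential-conditional construction
sim_deltas <- function(dcons, tau) {
  delta <- numeric(length(dcons))
  resid <- 0
  for (j in seq_along(dcons)) {
    m <- dcons[j] + if (j > 1) resid / j else 0
    v <- tau^2 * (j + 1) / (2 * j)
    delta[j] <- stats::rnorm(1, m, sqrt(v))
    resid <- resid + delta[j] - dcons[j]
  }
  delta
}

#' Simulate a contrast-level evidence network
#'
#' Per trial, trial effects are drawn around the true consistency
#' contrasts with sd `tau_true` (0.5 tau^2 correlated within multi-arm
#' trials) and observed log effects around the trial effects with the
#' layout's standard errors.  Deterministic given `truth$seed`.
#'
#' @param truth a [sim_truth()].
#' @return An `evidence_network` whose attribute `"truth"` is `truth`.
#' @export
simulate_contrast_network <- function(truth) {
  set.seed(truth$seed)
  arms <- list(); cts <- list()
  for (i in seq_along(truth$layout)) {
    tr <- truth$layout[[i]]
    tid <- sprintf("sim%02d", i)
    if (is.null(tr$se))
      stop("layout trial ", i, " has no contrast standard errors")
    dcons <- sim_dcon(truth, tr$comparators, tr$baseline)
    delta <- sim_deltas(dcons, truth$tau_true)
    y <- stats::rnorm(length(delta), delta, tr$se)
    n <- if (!is.null(tr$n)) tr$n else rep(100, 1 + length(tr$comparators))
    arms[[i]] <- data.frame(trial_id = tid,
                            treatment = c(tr$baseline, tr$comparators),
                            n_enrolled = n, stringsAsFactors = FALSE)
    cts[[i]] <- data.frame(trial_id = tid, baseline = tr$baseline,
                           treatment = tr$comparators,
                           outcome = truth$outcome, y = y, se = tr$se,
                           stringsAsFactors = FALSE)
  }
  net <- evidence_network(sim_treatment_frame(truth$treatments),
                          do.call(rbind, arms), do.call(rbind, cts),
                          reference = truth$treatments[1L])
  comps <- network_components(net, truth$outcome)
  if (length(comps) > 1L)
    stop("layout comparison graph disconnected: ",
         paste(vapply(comps, paste, "", collapse = "+"), collapse = " | "))
  attr(net, "truth") <- truth
  net
}

#' Simulate an arm-level adverse-event network
#'
#' Per trial, a baseline log odds is drawn from
#' `Normal(baseline_logodds, baseline_sd^2)` and each arm's event count
#' from `Binomial(n, plogis(mu + d_contrast))` (plus a between-trial
#' effect with sd `tau_true` when positive).  Counts are written to the
#' `ae_high` column (with `ae_any` set equal so the arm invariants
#' hold); the network carries no survival contrasts.
#'
#' @param truth a [sim_truth()]; every layout trial must supply per-arm
#'   sizes `n` (baseline first).
#' @return An `evidence_network` with attribute `"truth"`.
#' @export
simulate_ae_network <- function(truth) {
  set.seed(truth$seed + 1L)   # distinct stream from the contrast draws
  arms <- list()
  for (i in seq_along(truth$layout)) {
    tr <- truth$layout[[i]]
    if (is.null(tr$n))
      stop("layout trial ", i, " has no arm sizes")
    tid <- sprintf("sim%02d", i)
    mu <- stats::rnorm(1, truth$baseline_logodds, truth$baseline_sd)
    dcons <- c(0, sim_dcon(truth, tr$comparators, tr$baseline))
    if (truth$tau_true > 0)
      dcons <- c(0, sim_deltas(dcons[-1L], truth$tau_true))
    p <- stats::plogis(mu + dcons)
    r <- stats::rbinom(length(p), tr$n, p)
    arms[[i]] <- data.frame(trial_id = tid,
                            treatment = c(tr$baseline, tr$comparators),
                            n_enrolled = tr$n, ae_any = r, ae_high = r,
                            stringsAsFactors = FALSE)
  }
  net <- evidence_network(sim_treatment_frame(truth$treatments),
                          do.call(rbind, arms),
                          data.frame(trial_id = character(),
                                     baseline = character(),
                                     treatment = character(),
                                     outcome = character(), y = numeric(),
                                     se = numeric(),
                                     stringsAsFactors = FALSE),
                          reference = truth$treatments[1L])
  attr(net, "truth") <- truth
  net
}

#' Parameter-recovery experiment over replicated synthetic networks
#'
#' Draws `replicates` independent networks from `truth` (one root seed
#' spawns one sub-seed per replicate, so any replicate can be re-run in
#' isolation), fits the requested model to each, and summarizes
#' per-parameter bias, RMSE and empirical 95% credible-interval
#' coverage of the true basic parameters.
#'
#' @param replicates number of replicates (>= 2; >= 20 recommended for
#'   stable coverage).
#' @param truth a [sim_truth()].
#' @param likelihood `"contrast_normal"` (via
#'   [simulate_contrast_network()]) or `"arm_binomial"` (via
#'   [simulate_ae_network()], fitted on the `AE_high` counts).
#' @param effect fixed or random treatment effects for the fitted model.
#' @param chains,burn_in,keep,thin sampling schedule per fit (reduced
#'   defaults keep a replicate cheap).
#' @param root_seed seed of the replicate-seed stream.
#' @return Object of class `recovery_report`: data.frame (one row per
#'   basic parameter) with `truth`, `bias`, `mc_se` (Monte-Carlo
#'   standard error of the bias), `rmse`, `coverage`, plus attributes
#'   `replicates` and `tau_summary` (random-effects fits).
#' @export
recovery_report <- function(replicates, truth,
                            likelihood = c("contrast_normal",
                                           "arm_binomial"),
                            effect = c("fixed", "random"),
                            chains = 2, burn_in = 3000, keep = 1500,
                            thin = 3, root_seed = 42L) {
  likelihood <- match.arg(likelihood)
  effect <- match.arg(effect)
  if (replicates < 2) stop("need at least 2 replicates")
  set.seed(root_seed)
  seeds <- sample.int(.Machine$integer.max - 1L, replicates)
  pars <- truth$treatments[-1L]
  est <- lo <- hi <- matrix(NA_real_, replicates, length(pars),
                            dimnames = list(NULL, pars))
  tau_med <- numeric(replicates)
  outcome <- if (likelihood == "contrast_normal") truth$outcome else "AE_high"
  for (r in seq_len(replicates)) {
    tr <- truth; tr$seed <- seeds[r]
    net <- if (likelihood == "contrast_normal")
      simulate_contrast_network(tr) else simulate_ae_network(tr)
    fit <- nma(net, outcome = outcome, effect = effect, chains = chains,
               burn_in = burn_in, keep = keep, thin = thin,
               seed = seeds[r])
    d <- fit$draws[, fit$design$d_names, drop = FALSE]
    colnames(d) <- fit$design$treatments[-1L]
    q <- apply(d[, pars, drop = FALSE], 2, stats::quantile,
               probs = c(0.025, 0.5, 0.975))
    est[r, ] <- q[2, ]; lo[r, ] <- q[1, ]; hi[r, ] <- q[3, ]
    tau_med[r] <- if (effect == "random")
      stats::median(fit$draws[, "tau"]) else NA_real_
  }
  dt <- truth$d_true[pars]
  err <- sweep(est, 2, dt)
  cov <- colMeans(sweep(lo, 2, dt) <= 0 & sweep(hi, 2, dt) >= 0)
  out <- data.frame(parameter = pars, truth = unname(dt),
                    bias = colMeans(err),
                    mc_se = apply(err, 2, stats::sd) / sqrt(replicates),
                    rmse = sqrt(colMeans(err^2)),
                    coverage = unname(cov), stringsAsFactors = FALSE)
  structure(out, class = c("recovery_report", "data.frame"),
            replicates = replicates,
            tau_summary = if (effect == "random")
              c(mean = mean(tau_med), sd = stats::sd(tau_med)) else NULL)
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Parameter recovery over", attr(x, "replicates"), "replicates:\n")
  print(cbind(x["parameter"], round(x[-1L], 4)), row.names = FALSE)
  ts <- attr(x, "tau_summary")
  if (!is.null(ts))
    cat("tau posterior median: mean", round(ts["mean"], 3),
        "sd", round(ts["sd"], 3), "\n")
  invisible(x)
}
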