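#' Build the design of a mixed-treatment-comparison model
#'
#' Maps an evidence network onto the basic-parameter formulation: one
#' log relative effect `d[t]` per non-reference treatment, every observed
#' contrast `b -> k` expressed through the consistency equation
#' `d[k] - d[b]`, and (for random-effects models) one trial-specific
#' effect per non-baseline unit with the 0.5 tau^2 within-trial
#' correlation.
#'
#' @param network an [evidence_network()].
#' @param outcome outcome label: `"PFS"` or `"OS"` select the
#'   contrast-normal likelihood on log hazard ratios; `"AE_any"` /
#'   `"AE_high"` select the arm-level binomial likelihood on the
#'   corresponding adverse-event counts.
#' @param effect `"fixed"` or `"random"` treatment effects.
#' @param reference reference treatment id (defaults to the network's).
#' @param prior_sd_d prior standard deviation of the normal priors on
#'   basic parameters and trial baselines (log scale).
#' @param prior_tau_upper upper bound of the uniform prior on the
#'   between-trial standard deviation; defaults to 2 for log hazard
#'   ratios and 5 for log odds.
#' @return An object of class `nma_design`.
#' @export
build_design <- function(network, outcome = "PFS",
                         effect = c("fixed", "random"),
                         reference = network$reference,
                         prior_sd_d = 15, prior_tau_upper = NULL) {
  effect <- match.arg(effect)
  likelihood <- if (outcome %in% c("AE_any", "AE_high"))
    "arm_binomial" else "contrast_normal"
  if (is.null(prior_tau_upper))
    prior_tau_upper <- if (likelihood == "contrast_normal") 2 else 5

  if (likelihood == "contrast_normal") {
    ct <- network$contrasts[network$contrasts$outcome == outcome, ,
                            drop = FALSE]
    if (!nrow(ct)) stop("no contrasts for outcome ", outcome)
    comps <- network_components(network, outcome)
    if (length(comps) > 1L)
      stop("network disconnected for ", outcome, ": components ",
           paste(vapply(comps, paste, "", collapse = "+"), collapse = " | "))
    trts <- unique(c(reference, ct$baseline, ct$treatment))
    trts <- trts[trts %in% c(reference, unique(c(ct$baseline, ct$treatment)))]
    if (!reference %in% c(ct$baseline, ct$treatment))
      stop("reference treatment ", reference, " absent from ", outcome,
           " network")
    ct <- ct[order(ct$trial_id), , drop = FALSE]
    trial_ids <- unique(ct$trial_id)
    pos <- stats::ave(seq_len(nrow(ct)), ct$trial_id, FUN = seq_along)
    idx <- function(t) match(t, trts) - 1L
    dat <- list(likelihood = 0L, random = as.integer(effect == "random"),
                c_t = idx(ct$treatment), c_b = idx(ct$baseline),
                c_y = ct$y, c_se = ct$se,
                a_trial = integer(), a_t = integer(), a_b = integer(),
                a_unit = integer(), a_r = numeric(), a_n = numeric(),
                u_trial = match(ct$trial_id, trial_ids) - 1L,
                u_pos = as.integer(pos),
                u_t = idx(ct$treatment), u_b = idx(ct$baseline),
                n_d = length(trts) - 1L, n_trial = length(trial_ids),
                n_unit = nrow(ct),
                prior_sd_d = prior_sd_d, tau_upper = prior_tau_upper)
    arms <- network$arms[network$arms$trial_id %in% trial_ids, , drop = FALSE]
  } else {
    col <- if (outcome == "AE_any") "ae_any" else "ae_high"
    a <- network$arms[!is.na(network$arms[[col]]), , drop = FALSE]
    if (!nrow(a)) stop("no adverse-event counts for outcome ", outcome)
    # trial baseline: the trial's contrast baseline when known, else the
    # first listed arm
    base_of <- function(tid) {
      b <- unique(network$contrasts$baseline[network$contrasts$trial_id == tid])
      if (length(b) == 1L) b else a$treatment[a$trial_id == tid][1L]
    }
    trial_ids <- unique(a$trial_id)
    bases <- vapply(trial_ids, base_of, "")
    ord <- order(match(a$trial_id, trial_ids),
                 a$treatment != bases[match(a$trial_id, trial_ids)])
    a <- a[ord, , drop = FALSE]
    # connectivity on the implied comparison graph
    cg <- data.frame(trial_id = a$trial_id,
                     baseline = bases[match(a$trial_id, trial_ids)],
                     treatment = a$treatment, outcome = outcome,
                     y = 0, se = 1, stringsAsFactors = FALSE)
    cg <- cg[cg$baseline != cg$treatment, , drop = FALSE]
    tmpnet <- evidence_network(network$treatments,
                               a[, c("trial_id", "treatment", "n_enrolled")],
                               cg, reference, validate = FALSE)
    comps <- network_components(tmpnet, outcome)
    if (length(comps) > 1L)
      stop("network disconnected for ", outcome, ": components ",
           paste(vapply(comps, paste, "", collapse = "+"), collapse = " | "))
    trts <- unique(c(reference, bases, a$treatment))
    idx <- function(t) match(t, trts) - 1L
    is_base <- a$treatment == bases[match(a$trial_id, trial_ids)]
    # a trial may list its baseline treatment once only
    unit <- rep.int(-1L, nrow(a))
    unit[!is_base] <- seq_len(sum(!is_base)) - 1L
    ua <- which(!is_base)
    dat <- list(likelihood = 1L, random = as.integer(effect == "random"),
                c_t = integer(), c_b = integer(),
                c_y = numeric(), c_se = numeric(),
                a_trial = match(a$trial_id, trial_ids) - 1L,
                a_t = idx(a$treatment),
                a_b = idx(bases[match(a$trial_id, trial_ids)]),
                a_unit = unit, a_r = a[[col]], a_n = a$n_enrolled,
                u_trial = match(a$trial_id[ua], trial_ids) - 1L,
                u_pos = as.integer(stats::ave(seq_along(ua), a$trial_id[ua],
                                              FUN = seq_along)),
                u_t = idx(a$treatment[ua]),
                u_b = idx(bases[match(a$trial_id[ua], trial_ids)]),
                n_d = length(trts) - 1L, n_trial = length(trial_ids),
                n_unit = length(ua),
                prior_sd_d = prior_sd_d, tau_upper = prior_tau_upper)
    ct <- cg
    arms <- a
  }

  d_names <- paste0("d[", trts[-1L], "]")
  par_names <- d_names
  if (effect == "random") par_names <- c(par_names, "tau")
  if (likelihood == "arm_binomial")
    par_names <- c(par_names, paste0("mu[", trial_ids, "]"))
  if (effect == "random")
    par_names <- c(par_names, paste0("delta[", seq_len(dat$n_unit), "]"))

  structure(list(treatments = trts, reference = reference,
                 reportable = network$treatments,
                 outcome = outcome, likelihood = likelihood,
                 effect = effect, trial_ids = trial_ids,
                 contrasts = ct, arms = arms, dat = dat,
                 d_names = d_names, par_names = par_names,
                 prior_sd_d = prior_sd_d,
                 prior_tau_upper = prior_tau_upper),
            class = "nma_design")
}

#' @export
print.nma_design <- function(x, ...) {
  cat("MTC design (", x$likelihood, ", ", x$effect, " effects) for ",
      x$outcome, "\n", sep = "")
  cat(length(x$treatments), "treatments,", x$dat$n_trial, "trials,",
      x$dat$n_unit, "likelihood units\n")
  cat("Basic parameters:", paste(x$d_names, collapse = ", "), "\n")
  invisible(x)
}

#' Log posterior density of a mixed-treatment-comparison state
#'
#' Reference implementation in plain R of the density the compiled
#' sampler targets; useful for inspection and testing.  Returns `-Inf`
#' (not an error) for states outside the prior support, e.g. `tau`
#' beyond its uniform bound.
#'
#' @param design an [build_design()] result.
#' @param d numeric vector of basic parameters, in `design$d_names`
#'   order.
#' @param tau between-trial standard deviation (random-effects models).
#' @param delta per-unit trial effects (random-effects models).
#' @param mu per-trial baseline log odds (binomial likelihood).
#' @return Scalar log density (unnormalized).
#' @export
log_posterior <- function(design, d, tau = NULL, delta = NULL, mu = NULL) {
  dat <- design$dat
  random <- dat$random == 1L
  if (random && (is.null(tau) || is.null(delta)))
    stop("random-effects state needs tau and delta")
  if (random && (tau <= 0 || tau >= dat$tau_upper)) return(-Inf)
  dv <- function(i) ifelse(i == 0L, 0, d[pmax(i, 1L)])
  dcon <- function(t, b) dv(t) - dv(b)
  lp <- sum(stats::dnorm(d, 0, dat$prior_sd_d, log = TRUE))
  if (dat$likelihood == 0L) {
    theta <- if (random) delta else dcon(dat$c_t, dat$c_b)
    lp <- lp + sum(stats::dnorm(dat$c_y, theta, dat$c_se, log = TRUE))
  } else {
    if (is.null(mu)) stop("binomial likelihood needs mu")
    eta <- mu[dat$a_trial + 1L]
    off <- if (random) ifelse(dat$a_unit >= 0L, delta[pmax(dat$a_unit, 0L) + 1L], 0)
      else dcon(dat$a_t, dat$a_b)
    eta <- eta + ifelse(dat$a_unit >= 0L, off, 0)
    lp <- lp + sum(stats::dbinom(dat$a_r, dat$a_n, stats::plogis(eta),
                                 log = TRUE))
    lp <- lp + sum(stats::dnorm(mu, 0, dat$prior_sd_d, log = TRUE))
  }
  if (random) {
    for (tr in unique(dat$u_trial)) {
      us <- which(dat$u_trial == tr)
      resid <- 0
      for (j in seq_along(us)) {
        u <- us[j]
        dc <- dcon(dat$u_t[u], dat$u_b[u])
        m <- dc + if (j > 1) resid / j else 0
        v <- tau^2 * (j + 1) / (2 * j)
        lp <- lp + stats::dnorm(delta[u], m, sqrt(v), log = TRUE)
        resid <- resid + delta[u] - dc
      }
    }
  }
  lp
}

#' Fit a Bayesian network meta-analysis
#'
#' The main fitting function: builds the consistency design for the
#' requested outcome, runs an adaptive random-walk Metropolis-within-
#' Gibbs sampler over the basic parameters (plus between-trial sd,
#' trial baselines and trial effects as the model requires), and
#' returns posterior draws with convergence and fit diagnostics (DIC).
#'
#' The default schedule — 3 chains, 10,000-iteration adaptation/burn-in,
#' 10,000 retained draws per chain at a thinning interval of 50 —
#' matches the published analysis.
#'
#' @inheritParams build_design
#' @param chains number of chains (>= 2 for convergence checks).
#' @param burn_in iterations discarded (and used for step-size
#'   adaptation) per chain.
#' @param keep retained draws per chain (after thinning).
#' @param thin thinning interval.
#' @param adapt adaptation window (iterations between step-size updates
#'   during burn-in).
#' @param seed integer seed; the fit is fully reproducible given the
#'   seed.
#' @param psrf_threshold potential-scale-reduction threshold above which
#'   the fit is flagged (with a warning) as non-converged.
#' @return An object of class `nma_fit` with elements `design`, `draws`
#'   (all chains row-bound), `chains` (per-chain matrices), `accept`,
#'   `dic` (`Dbar`, `pD`, `DIC`), `psrf`, `converged`, `seed`, and the
#'   sampling schedule.
#' @export
#' @examples
#' \donttest{
#' net <- load_trial_table(melnma_example(), outcome = "PFS")
#' net <- merge_dose_arms(net, "pool")
#' fit <- nma(net, "PFS", effect = "fixed", keep = 1000, thin = 5,
#'            burn_in = 2000, seed = 1)
#' summary(fit)
#' }
nma <- function(network, outcome = "PFS", effect = c("fixed", "random"),
                reference = network$reference, prior_sd_d = 15,
                prior_tau_upper = NULL, chains = 3, burn_in = 10000,
                keep = 10000, thin = 50, adapt = 50, seed = NULL,
                psrf_threshold = 1.05) {
  effect <- match.arg(effect)
  if (chains < 2) warning("fewer than 2 chains: no convergence check")
  design <- build_design(network, outcome, effect, reference,
                         prior_sd_d, prior_tau_upper)
  if (!is.null(seed)) set.seed(seed)
  dat <- design$dat
  random <- dat$random == 1L
  binom <- dat$likelihood == 1L

  mu_start <- if (binom) {
    base <- dat$a_unit < 0L
    stats::qlogis((dat$a_r[base] + 0.5) / (dat$a_n[base] + 1))[
      order(dat$a_trial[base])]
  } else numeric()

  chain_list <- vector("list", chains)
  accept <- NULL
  for (ch in seq_len(chains)) {
    init_d <- stats::rnorm(dat$n_d, 0, 0.5)
    init_tau <- if (random)
      stats::runif(1, 0.025 * dat$tau_upper,
                   0.5 * dat$tau_upper) else 0
    dv <- c(0, init_d)
    init_delta <- if (random)
      dv[dat$u_t + 1L] - dv[dat$u_b + 1L] else numeric()
    init_mu <- if (binom) mu_start + stats::rnorm(length(mu_start), 0, 0.2)
      else numeric()
    res <- mtc_chain_cpp(dat, init_d, init_tau, init_delta, init_mu,
                         burn_in, keep, thin, adapt)
    colnames(res$draws) <- c(design$par_names, "deviance")
    chain_list[[ch]] <- res$draws
    accept <- res$accept
  }
  draws <- do.call(rbind, chain_list)

  # DIC: pD = Dbar - D(posterior mean)
  Dbar <- mean(draws[, "deviance"])
  pm <- colMeans(draws)
  nd <- dat$n_d
  pm_d <- pm[seq_len(nd)]
  pm_tau <- if (random) pm[["tau"]] else 0
  pm_mu <- if (binom) pm[paste0("mu[", design$trial_ids, "]")] else numeric()
  pm_delta <- if (random)
    pm[paste0("delta[", seq_len(dat$n_unit), "]")] else numeric()
  Dhat <- mtc_deviance_cpp(dat, pm_d, pm_tau, pm_delta, pm_mu)
  pD <- Dbar - Dhat
  dic <- list(Dbar = Dbar, pD = pD, DIC = Dbar + pD)

  report <- setdiff(design$par_names,
                    paste0("delta[", seq_len(max(dat$n_unit, 1L)), "]"))
  psrf <- gelman_rubin(lapply(chain_list, function(m)
    m[, report, drop = FALSE]))
  converged <- all(psrf < psrf_threshold, na.rm = TRUE)
  if (!converged)
    warning("possible non-convergence: max PSRF = ",
            formatC(max(psrf, na.rm = TRUE), digits = 4, format = "f"))

  structure(list(design = design, draws = draws, chains = chain_list,
                 accept = accept, dic = dic, psrf = psrf,
                 converged = converged, seed = seed,
                 schedule = list(chains = chains, burn_in = burn_in,
                                 keep = keep, thin = thin, adapt = adapt)),
            class = "nma_fit")
}

#' Posterior draws of the basic parameters
#' @param fit an `nma_fit`.
#' @return Matrix (draws x treatments) of `d` including a zero column
#'   for the reference, in design treatment order.
#' @export
basic_draws <- function(fit) {
  d <- fit$draws[, fit$design$d_names, drop = FALSE]
  out <- cbind(0, d)
  colnames(out) <- fit$design$treatments
  out
}

#' @export
coef.nma_fit <- function(object, ...) {
  d <- object$draws[, object$design$d_names, drop = FALSE]
  stats::setNames(apply(d, 2, stats::median), object$design$d_names)
}

#' @export
print.nma_fit <- function(x, ...) {
  cat("Bayesian network meta-analysis (", x$design$effect, " effects, ",
      x$design$likelihood, ") — outcome ", x$design$outcome, "\n", sep = "")
  s <- x$schedule
  cat(s$chains, " chains x ", s$keep, " retained (burn-in ", s$burn_in,
      ", thin ", s$thin, "); ", ifelse(x$converged, "converged",
      "NOT converged"), ", max PSRF ",
      formatC(max(x$psrf, na.rm = TRUE), digits = 3, format = "f"),
      "\n", sep = "")
  cat("DIC ", formatC(x$dic$DIC, digits = 1, format = "f"), " (Dbar ",
      formatC(x$dic$Dbar, digits = 1, format = "f"), ", pD ",
      formatC(x$dic$pD, digits = 1, format = "f"), ")\n", sep = "")
  cat("\nBasic parameters (posterior median log effect vs ",
      x$design$reference, "):\n", sep = "")
  print(round(coef(x), 3))
  invisible(x)
}

#' @export
summary.nma_fit <- function(object, ...) {
  pars <- c(object$design$d_names,
            if (object$design$effect == "random") "tau")
  qs <- t(apply(object$draws[, pars, drop = FALSE], 2, stats::quantile,
                probs = c(0.5, 0.025, 0.975)))
  out <- data.frame(median = qs[, 1], lower = qs[, 2], upper = qs[, 3],
                    psrf = object$psrf[pars])
  structure(list(table = out, dic = object$dic,
                 design = object$design), class = "summary.nma_fit")
}

#' @export
print.summary.nma_fit <- function(x, ...) {
  cat("Posterior summary (log scale), outcome ", x$design$outcome,
      ", ", x$design$effect, " effects:\n", sep = "")
  print(round(x$table, 4))
  cat("DIC ", formatC(x$dic$DIC, digits = 1, format = "f"), " (pD ",
      formatC(x$dic$pD, digits = 1, format = "f"), ")\n", sep = "")
  invisible(x)
}

#' Forest-style plot of basic parameters
#' @param x an `nma_fit`.
#' @param exponentiate show ratios instead of log effects.
#' @param ... passed to [graphics::plot.default()].
#' @export
plot.nma_fit <- function(x, exponentiate = TRUE, ...) {
  d <- x$draws[, x$design$d_names, drop = FALSE]
  q <- apply(d, 2, stats::quantile, probs = c(0.025, 0.5, 0.975))
  if (exponentiate) q <- exp(q)
  n <- ncol(q)
  graphics::plot(q[2, ], seq_len(n), xlim = range(q),
                 log = if (exponentiate) "x" else "",
                 yaxt = "n", pch = 19, xlab = if (exponentiate)
                   "ratio vs reference" else "log effect vs reference",
                 ylab = "", ...)
  graphics::segments(q[1, ], seq_len(n), q[3, ], seq_len(n))
  graphics::abline(v = if (exponentiate) 1 else 0, lty = 2)
  graphics::axis(2, at = seq_len(n),
                 labels = x$design$treatments[-1L], las = 1)
  invisible(x)
}

#' All-pairs league table from posterior draws
#'
#' For every ordered treatment pair the posterior median and 2.5/97.5
#' percentiles of `exp(d[col] - d[row])`: the column treatment compared
#' with the row treatment, ratios below 1 favoring the column treatment
#' for hazard/odds of an undesirable event.  Only reportable treatments
#' are tabulated unless `include` says otherwise.
#'
#' @param fit an `nma_fit`.
#' @param include treatment ids to tabulate; default all reportable
#'   treatments in the design.
#' @return Object of class `league_table`: list of `median`, `lower`,
#'   `upper` and `significant` matrices (significance = 95% credible
#'   interval excluding 1).
#' @export
league_table <- function(fit, include = NULL) {
  bd <- basic_draws(fit)
  if (is.null(include)) {
    rep_ids <- fit$design$reportable$id[fit$design$reportable$reportable]
    include <- intersect(colnames(bd), rep_ids)
  }
  bd <- bd[, include, drop = FALSE]
  k <- ncol(bd)
  med <- lo <- hi <- matrix(1, k, k, dimnames = list(include, include))
  sig <- matrix(FALSE, k, k, dimnames = list(include, include))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    diff <- bd[, j] - bd[, i]          # column j vs row i
    med[i, j] <- exp(stats::median(diff))
    qq <- stats::quantile(diff, c(0.025, 0.975), names = FALSE)
    lo[i, j] <- exp(qq[1]); hi[i, j] <- exp(qq[2])
    sig[i, j] <- qq[1] > 0 || qq[2] < 0
  }
  structure(list(median = med, lower = lo, upper = hi, significant = sig,
                 outcome = fit$design$outcome),
            class = "league_table")
}

#' Extract one league-table comparison
#' @param lt a `league_table`.
#' @param col,row treatment ids: the ratio reported is `col` vs `row`.
#' @return Named vector `median`, `lower`, `upper`.
#' @export
league_entry <- function(lt, col, row) {
  c(median = lt$median[row, col], lower = lt$lower[row, col],
    upper = lt$upper[row, col])
}

#' @export
print.league_table <- function(x, digits = 2, ...) {
  k <- nrow(x$median)
  out <- matrix("—", k, k, dimnames = dimnames(x$median))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    out[i, j] <- sprintf("%.*f (%.*f-%.*f)%s", digits, x$median[i, j],
                         digits, x$lower[i, j], digits, x$upper[i, j],
                         if (x$significant[i, j]) "*" else "")
  }
  cat("League table (column vs row, ", x$outcome,
      "; * = 95% CrI excludes 1):\n", sep = "")
  print(out, quote = FALSE)
  invisible(x)
}
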