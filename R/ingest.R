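#' Standard error of a log effect from a ratio confidence interval
#'
#' Published hazard or odds ratios are usually accompanied by a 95% CI on
#' the ratio scale; the standard error of the log effect is recovered as
#' `(log(upper) - log(lower)) / (2 * z)` with `z` the normal quantile at
#' the interval's coverage.
#'
#' @param lower,upper positive CI bounds on the ratio scale,
#'   `lower < upper`.  Vectorized.
#' @param level interval coverage (default 0.95).
#' @return Standard error(s) of the log effect.
#' @export
#' @examples
#' se_from_ci(0.45, 0.73)     # pembrolizumab 2 mg/kg PFS contrast
se_from_ci <- function(lower, upper, level = 0.95) {
  if (any(!is.finite(lower) | !is.finite(upper) | lower <= 0))
    stop("CI bounds must be positive and finite")
  if (any(lower >= upper))
    stop("malformed CI: lower >= upper")
  z <- stats::qnorm((1 + level) / 2)
  (log(upper) - log(lower)) / (2 * z)
}

#' Load a trial evidence table
#'
#' Reads a comma-separated arm-level table (one row per arm; columns
#' `trial_id`, `author_year`, `treatment`, `n`, `hr`, `ci_low`,
#' `ci_high`, `ae_any`, `ae_high`, `outcome`; empty cells mean missing)
#' and assembles a validated [evidence_network()].  Within a trial the
#' reference arm is the row with `hr = 1` and no CI; rows with an
#' entirely missing `hr` contribute an arm (enrolment, adverse-event
#' counts) but no contrast.
#'
#' @param path path to the delimited file.
#' @param outcome outcome label attached to contrasts whose `outcome`
#'   cell is empty.
#' @param treatments treatment registry; defaults to
#'   [melanoma_treatments()].
#' @param level CI coverage used by [se_from_ci()].
#' @return An `evidence_network`.
#' @export
load_trial_table <- function(path, outcome = "PFS",
                             treatments = melanoma_treatments(),
                             level = 0.95) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (nrow(tab) == 0L) stop("no trials: empty evidence table")
  need <- c("trial_id", "treatment", "n")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  num <- function(x) suppressWarnings(as.numeric(x))
  blank <- function(x) is.na(x) | !nzchar(trimws(x))
  if (is.null(tab$outcome)) tab$outcome <- ""
  tab$outcome[blank(tab$outcome)] <- outcome

  arms <- data.frame(trial_id = tab$trial_id,
                     author_year = if ("author_year" %in% names(tab))
                       tab$author_year else tab$trial_id,
                     treatment = tab$treatment,
                     n_enrolled = num(tab$n),
                     dose_label = if ("dose_label" %in% names(tab))
                       tab$dose_label else NA_character_,
                     ae_any = if ("ae_any" %in% names(tab))
                       num(tab$ae_any) else NA_real_,
                     ae_high = if ("ae_high" %in% names(tab))
                       num(tab$ae_high) else NA_real_,
                     stringsAsFactors = FALSE)

  has_hr <- !blank(tab$hr)
  has_ci <- !blank(tab$ci_low) & !blank(tab$ci_high)
  is_ref <- has_hr & !has_ci & num(tab$hr) == 1
  rows <- list()
  for (tid in unique(tab$trial_id)) {
    idx <- which(tab$trial_id == tid)
    ref <- idx[is_ref[idx]]
    eff <- idx[has_hr[idx] & has_ci[idx]]
    if (!length(eff)) next
    if (length(ref) != 1L)
      stop("trial ", tid, ": expected exactly one reference arm ",
           "(hr = 1, no CI), found ", length(ref))
    for (i in eff) {
      lo <- num(tab$ci_low[i]); hi <- num(tab$ci_high[i])
      if (!is.finite(lo) || !is.finite(hi) || lo <= 0 || lo >= hi)
        stop("trial ", tid, ", arm '", tab$treatment[i],
             "': malformed CI (", tab$ci_low[i], ", ", tab$ci_high[i], ")")
      rows[[length(rows) + 1L]] <- data.frame(
        trial_id = tid, baseline = tab$treatment[ref],
        treatment = tab$treatment[i], outcome = tab$outcome[i],
        y = log(num(tab$hr[i])), se = se_from_ci(lo, hi, level),
        stringsAsFactors = FALSE)
    }
  }
  contrasts <- if (length(rows)) do.call(rbind, rows) else
    data.frame(trial_id = character(), baseline = character(),
               treatment = character(), outcome = character(),
               y = numeric(), se = numeric(), stringsAsFactors = FALSE)
  evidence_network(treatments, arms, contrasts)
}

#' Path to the shipped melanoma PFS evidence table
#'
#' The hand-transcribed published trial table: 12 randomized trials of
#' immune-checkpoint-inhibitor regimens, of which 10 report a
#' progression-free-survival hazard ratio with 95% CI.  Two trials
#' (ipilimumab plus dacarbazine vs ipilimumab; ipilimumab plus
#' budesonide vs ipilimumab) report no usable HR and contribute arms
#' only.
#'
#' @param file one of `"melanoma_pfs.csv"` or
#'   `"risk_flags_synthetic.csv"`.
#' @return Absolute path to the installed file.
#' @export
melnma_example <- function(file = "melanoma_pfs.csv") {
  p <- system.file("extdata", file, package = "melnma")
  if (!nzchar(p)) stop("no such example file: ", file)
  p
}

#' Merge same-treatment dose arms within a trial
#'
#' Two trials randomized two pembrolizumab dose groups against one
#' control; the network treats pembrolizumab as a single node.  Under
#' `policy = "pool"` the same-treatment contrasts sharing a baseline are
#' combined by fixed-effect inverse-variance pooling on the log scale and
#' the arms' enrolments (and AE counts) are summed; `"keep_first"`
#' retains only the first-listed dose arm; `"keep_all_as_distinct"`
#' leaves the network untouched.
#'
#' @param net an `evidence_network`.
#' @param policy `"pool"`, `"keep_first"` or `"keep_all_as_distinct"`.
#' @return A new `evidence_network`; pooled contrasts record their
#'   provenance in attribute `"merged"`.
#' @export
merge_dose_arms <- function(net, policy = c("pool", "keep_first",
                                            "keep_all_as_distinct")) {
  policy <- match.arg(policy)
  if (policy == "keep_all_as_distinct") return(net)
  ct <- net$contrasts
  a <- net$arms
  key <- paste(ct$trial_id, ct$treatment, ct$outcome)
  dup <- unique(key[duplicated(key)])
  merged <- character()
  for (k in dup) {
    idx <- which(key == k)
    if (length(unique(ct$baseline[idx])) > 1L)
      stop("cannot pool dose arms with different baselines in ",
           ct$trial_id[idx[1L]])
    if (policy == "pool") {
      w <- 1 / ct$se[idx]^2
      ct$y[idx[1L]] <- sum(w * ct$y[idx]) / sum(w)
      ct$se[idx[1L]] <- 1 / sqrt(sum(w))
    } else {
      warning("keep_first: dropping ", length(idx) - 1L,
              " dose arm(s) in ", ct$trial_id[idx[1L]])
    }
    ct <- ct[-idx[-1L], , drop = FALSE]
    key <- paste(ct$trial_id, ct$treatment, ct$outcome)
    merged <- c(merged, k)
  }
  # collapse the corresponding arms
  akey <- paste(a$trial_id, a$treatment)
  adup <- unique(akey[duplicated(akey)])
  for (k in adup) {
    idx <- which(akey == k)
    if (policy == "pool") {
      a$n_enrolled[idx[1L]] <- sum(a$n_enrolled[idx])
      a$ae_any[idx[1L]] <- if (all(!is.na(a$ae_any[idx])))
        sum(a$ae_any[idx]) else NA_real_
      a$ae_high[idx[1L]] <- if (all(!is.na(a$ae_high[idx])))
        sum(a$ae_high[idx]) else NA_real_
      a$dose_label[idx[1L]] <- "pooled"
    }
    a <- a[-idx[-1L], , drop = FALSE]
    akey <- paste(a$trial_id, a$treatment)
  }
  out <- evidence_network(net$treatments, a, ct, net$reference)
  attr(out, "merged") <- merged
  out
}

#' Resolve auxiliary (non-reportable) treatment nodes
#'
#' The three-arm ipilimumab / ipilimumab-plus-gp100 / gp100 trial anchors
#' both of its published contrasts on the gp100-alone arm, a regimen the
#' network does not report on.  `"aux_node"` (default) keeps gp100 as a
#' likelihood-only node so the trial's within-trial randomization is
#' preserved.  `"rebase_independent"` instead differences the two
#' contrasts (`y = y1 - y2`, `se = sqrt(se1^2 + se2^2)`, treating them as
#' independent) into a single contrast between the two reportable arms
#' and drops the auxiliary arm.
#'
#' @param net an `evidence_network`.
#' @param policy `"aux_node"` or `"rebase_independent"`.
#' @return A new `evidence_network` (unchanged when no auxiliary
#'   treatment occurs).
#' @export
resolve_auxiliary_nodes <- function(net, policy = c("aux_node",
                                                    "rebase_independent")) {
  policy <- match.arg(policy)
  aux <- net$treatments$id[!net$treatments$reportable]
  if (policy == "aux_node" || !length(aux)) return(net)
  ct <- net$contrasts
  a <- net$arms
  for (tid in unique(ct$trial_id)) {
    idx <- which(ct$trial_id == tid & ct$baseline %in% aux)
    if (!length(idx)) next
    if (length(idx) != 2L)
      stop("rebase_independent expects exactly two contrasts against ",
           "the auxiliary baseline in trial ", tid)
    new <- ct[idx[1L], , drop = FALSE]
    new$baseline <- ct$treatment[idx[2L]]
    new$y <- ct$y[idx[1L]] - ct$y[idx[2L]]
    new$se <- sqrt(ct$se[idx[1L]]^2 + ct$se[idx[2L]]^2)
    ct <- rbind(ct[-idx, , drop = FALSE], new)
    a <- a[!(a$trial_id == tid & a$treatment %in% aux), , drop = FALSE]
  }
  ct <- ct[!(ct$baseline %in% aux | ct$treatment %in% aux), , drop = FALSE]
  evidence_network(net$treatments[net$treatments$reportable, , drop = FALSE],
                   a, ct, net$reference)
}

#' Read trial risk-of-bias flags
#'
#' @param path comma-separated file with columns `trial_id`, `low_risk`
#'   (`TRUE`/`FALSE` or 1/0).
#' @return Named logical vector, one element per trial.
#' @export
read_risk_flags <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stats::setNames(as.logical(tab$low_risk), tab$trial_id)
}

#' Restrict a network to low-risk-of-bias trials
#'
#' Sensitivity analysis: drop trials not flagged low-risk, then
#' re-validate connectivity for every outcome still present.  A
#' disconnected result is an error naming the separated components —
#' it is never silently fitted.
#'
#' @param net an `evidence_network`.
#' @param flags named logical vector (`trial_id -> low_risk`) covering
#'   every trial in the network, e.g. from [read_risk_flags()].
#' @return The restricted `evidence_network`.
#' @export
filter_low_risk <- function(net, flags) {
  trials <- unique(net$arms$trial_id)
  miss <- setdiff(trials, names(flags))
  if (length(miss))
    stop("risk flags missing for trial(s): ", paste(miss, collapse = ", "))
  keep <- trials[flags[trials]]
  a <- net$arms[net$arms$trial_id %in% keep, , drop = FALSE]
  ct <- net$contrasts[net$contrasts$trial_id %in% keep, , drop = FALSE]
  used <- unique(c(a$treatment, ct$baseline, ct$treatment, net$reference))
  tr <- net$treatments[net$treatments$id %in% used, , drop = FALSE]
  out <- evidence_network(tr, a, ct, net$reference)
  for (oc in unique(ct$outcome)) {
    comps <- network_components(out, oc)
    if (length(comps) > 1L)
      stop("low-risk subnetwork disconnected for ", oc, ": ",
           paste(vapply(comps, paste, "", collapse = "+"),
                 collapse = " | "))
  }
  out
}
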