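#' Construct an evidence network
#'
#' Bundles treatments, per-arm enrolment (and optional adverse-event
#' counts) and trial-level relative-effect contrasts into the validated
#' container every downstream model consumes.
#'
#' @param treatments data.frame with columns `id`, `label`, `reportable`
#'   (see [melanoma_treatments()]).
#' @param arms data.frame with columns `trial_id`, `treatment`,
#'   `n_enrolled`, and optionally `dose_label`, `ae_any`, `ae_high`.
#' @param contrasts data.frame with columns `trial_id`, `baseline`,
#'   `treatment`, `outcome`, `y` (log relative effect) and `se`.  May have
#'   zero rows (arm-level data only).
#' @param reference id of the network reference treatment.
#' @param validate check invariants (treatment codes known, `se > 0`,
#'   one baseline per trial, no duplicate contrasts).
#'
#' @return An object of class `evidence_network`: a list with elements
#'   `treatments`, `arms`, `contrasts` and `reference`.
#' @export
evidence_network <- function(treatments, arms, contrasts,
                             reference = reference_treatment(),
                             validate = TRUE) {
  contrasts <- as.data.frame(contrasts, stringsAsFactors = FALSE)
  arms <- as.data.frame(arms, stringsAsFactors = FALSE)
  if (!"dose_label" %in% names(arms)) arms$dose_label <- NA_character_
  if (!"ae_any" %in% names(arms)) arms$ae_any <- NA_real_
  if (!"ae_high" %in% names(arms)) arms$ae_high <- NA_real_
  net <- structure(
    list(treatments = treatments, arms = arms, contrasts = contrasts,
         reference = reference),
    class = "evidence_network"
  )
  if (validate) validate_network(net)
  net
}

#' Validate an evidence network
#'
#' Checks the structural invariants: unique treatment ids, a known
#' reference, arms and contrasts referring only to registered treatments,
#' positive enrolment, `0 <= ae_high <= ae_any <= n`, positive standard
#' errors, distinct baseline/comparator, a single shared baseline per
#' trial, and no duplicated (trial, baseline, comparator, outcome) rows.
#'
#' @param net an `evidence_network`.
#' @return `net`, invisibly; stops with an informative message otherwise.
#' @export
validate_network <- function(net) {
  tr <- net$treatments
  if (anyDuplicated(tr$id)) stop("duplicate treatment ids")
  if (!net$reference %in% tr$id)
    stop("reference treatment '", net$reference, "' not in treatment set")
  a <- net$arms
  if (nrow(a) == 0L) stop("no trials: network has no arms")
  bad <- setdiff(unique(c(a$treatment, net$contrasts$baseline,
                          net$contrasts$treatment)), tr$id)
  if (length(bad))
    stop("unknown treatment code(s): ", paste(bad, collapse = ", "))
  if (any(a$n_enrolled <= 0)) stop("n_enrolled must be positive")
  hasae <- !is.na(a$ae_any) & !is.na(a$ae_high)
  if (any(hasae & (a$ae_high > a$ae_any | a$ae_any > a$n_enrolled |
                     a$ae_high < 0)))
    stop("adverse-event counts must satisfy 0 <= ae_high <= ae_any <= n")
  ct <- net$contrasts
  if (nrow(ct)) {
    if (any(!is.finite(ct$se) | ct$se <= 0)) {
      i <- which(!is.finite(ct$se) | ct$se <= 0)[1L]
      stop("non-positive standard error in trial ", ct$trial_id[i])
    }
    if (any(ct$baseline == ct$treatment))
      stop("contrast with identical baseline and comparator")
    key <- paste(ct$trial_id, ct$baseline, ct$treatment, ct$outcome)
    if (anyDuplicated(key)) {
      # several same-pair contrasts are legitimate only while a trial
      # still carries several dose arms of one treatment
      dup <- key[duplicated(key)]
      for (k in unique(dup)) {
        i <- which(key == k)[1L]
        narm <- sum(a$trial_id == ct$trial_id[i] &
                      a$treatment == ct$treatment[i])
        if (narm < sum(key == k))
          stop("duplicate contrast: ", k)
      }
    }
    nb <- tapply(ct$baseline, paste(ct$trial_id, ct$outcome),
                 function(b) length(unique(b)))
    if (any(nb > 1L))
      stop("trial with more than one baseline: ",
           names(nb)[nb > 1L][1L])
  }
  invisible(net)
}

#' @export
print.evidence_network <- function(x, ...) {
  ct <- x$contrasts
  cat("Evidence network:",
      length(unique(x$arms$trial_id)), "trials,",
      nrow(x$arms), "arms,", nrow(ct), "contrasts\n")
  cat("Treatments (", sum(x$treatments$reportable), " reportable + ",
      sum(!x$treatments$reportable), " auxiliary): ",
      paste(x$treatments$id, collapse = ", "), "\n", sep = "")
  cat("Reference:", x$reference, "\n")
  if (nrow(ct)) {
    for (oc in unique(ct$outcome)) {
      conn <- if (is_connected(x, oc)) "connected" else "DISCONNECTED"
      cat("Outcome ", oc, ": ", sum(ct$outcome == oc), " contrasts, ",
          conn, "\n", sep = "")
    }
  }
  invisible(x)
}

#' Connected components of the comparison graph
#'
#' @param net an `evidence_network`.
#' @param outcome outcome label restricting the contrasts considered.
#' @return A list of character vectors, one per component, covering every
#'   treatment that appears in a contrast for the outcome.
#' @export
network_components <- function(net, outcome) {
  ct <- net$contrasts[net$contrasts$outcome == outcome, , drop = FALSE]
  nodes <- unique(c(ct$baseline, ct$treatment))
  if (!length(nodes)) return(list())
  comp <- stats::setNames(seq_along(nodes), nodes)
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(ct))) {
      a <- ct$baseline[i]; b <- ct$treatment[i]
      m <- min(comp[a], comp[b])
      if (comp[a] != m || comp[b] != m) {
        comp[comp == max(comp[a], comp[b])] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  unname(lapply(split(names(comp), comp), sort))
}

#' Is the comparison graph connected for an outcome?
#' @inheritParams network_components
#' @return Logical.
#' @export
is_connected <- function(net, outcome) {
  length(network_components(net, outcome)) == 1L
}

#' Serialize an evidence network to delimited text
#'
#' Writes the arm table (with each trial's baseline arm marked by
#' `hr = 1` and empty CI cells, and comparator arms carrying the
#' back-transformed relative effect) in the same comma-separated schema
#' [load_trial_table()] ingests, so that load -> serialize -> load is
#' lossless up to floating-point round-trip.
#'
#' @param net an `evidence_network`.
#' @param path file path to write.
#' @param level coverage of the confidence intervals used to re-express
#'   standard errors as CI bounds.
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(net, path, level = 0.95) {
  z <- stats::qnorm((1 + level) / 2)
  a <- net$arms
  out <- data.frame(trial_id = a$trial_id,
                    author_year = if ("author_year" %in% names(a))
                      a$author_year else a$trial_id,
                    treatment = a$treatment,
                    n = a$n_enrolled,
                    hr = NA_character_, ci_low = NA_character_,
                    ci_high = NA_character_,
                    ae_any = a$ae_any, ae_high = a$ae_high,
                    outcome = NA_character_,
                    stringsAsFactors = FALSE)
  ct <- net$contrasts
  fmt <- function(x) formatC(x, digits = 15, format = "g")
  taken <- logical(nrow(out))
  for (i in seq_len(nrow(ct))) {
    j <- which(out$trial_id == ct$trial_id[i] &
                 out$treatment == ct$treatment[i] & !taken)[1L]
    taken[j] <- TRUE
    out$hr[j] <- fmt(exp(ct$y[i]))
    out$ci_low[j] <- fmt(exp(ct$y[i] - z * ct$se[i]))
    out$ci_high[j] <- fmt(exp(ct$y[i] + z * ct$se[i]))
    out$outcome[j] <- ct$outcome[i]
    b <- which(out$trial_id == ct$trial_id[i] &
                 out$treatment == ct$baseline[i])[1L]
    out$hr[b] <- "1"
    out$outcome[b] <- ct$outcome[i]
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}
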