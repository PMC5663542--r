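#' Rank probability matrix (rankogram data)
#'
#' For each retained draw the included treatments are ordered by their
#' basic-parameter value — rank 1 best, where "best" depends on the
#' outcome's direction (`lower_better` for hazards and adverse-event
#' odds).  The matrix of empirical rank frequencies is doubly
#' stochastic: rows (treatments) and columns (ranks) each sum to 1.
#'
#' @param fit an `nma_fit`.
#' @param direction `"lower_better"` or `"higher_better"`.
#' @param include treatments to rank; defaults to the reportable
#'   treatments present in the design.
#' @param tie_seed seed for the module's own tie-breaking generator
#'   (ties are broken by a uniform random permutation; with continuous
#'   posteriors they have probability zero).
#' @return Object of class `rank_matrix`: matrix `P[t, j]` with
#'   attribute `direction`.
#' @export
rank_probabilities <- function(fit, direction = c("lower_better",
                                                  "higher_better"),
                               include = NULL, tie_seed = 1L) {
  direction <- match.arg(direction)
  bd <- basic_draws(fit)
  if (is.null(include)) {
    rep_ids <- fit$design$reportable$id[fit$design$reportable$reportable]
    include <- intersect(colnames(bd), rep_ids)
  }
  if (!length(include)) stop("empty treatment set")
  bd <- bd[, include, drop = FALSE]
  if (direction == "higher_better") bd <- -bd
  k <- ncol(bd)
  P <- matrix(0, k, k, dimnames = list(include, paste0("rank", seq_len(k))))
  rng <- local({
    state <- as.integer(tie_seed)
    function(n) {
      # Lehmer generator, local to tie-breaking
      out <- numeric(n)
      for (i in seq_len(n)) {
        state <<- as.integer((as.double(state) * 48271) %% 2147483647)
        out[i] <- state / 2147483647
      }
      out
    }
  })
  for (i in seq_len(nrow(bd))) {
    x <- bd[i, ]
    if (anyDuplicated(x)) {
      ord <- order(x, rng(k))          # random permutation within ties
      r <- match(seq_len(k), ord)
    } else {
      r <- rank(x)
    }
    P[cbind(seq_len(k), r)] <- P[cbind(seq_len(k), r)] + 1
  }
  P <- P / nrow(bd)
  structure(P, direction = direction, class = c("rank_matrix", "matrix"))
}

#' Cumulative rank score (SUCRA-style summary)
#'
#' The mean cumulative rank probability over ranks 1..(T-1): 1 when a
#' treatment is certainly best, 0 when certainly worst, 0.5 under a
#' uniform rank distribution.
#'
#' @param P a `rank_matrix` (or plain doubly stochastic matrix).
#' @return Named numeric vector of scores in [0, 1].
#' @export
cumulative_rank_score <- function(P) {
  k <- ncol(P)
  if (k == 1L) return(stats::setNames(1, rownames(P)))
  cum <- t(apply(unclass(P), 1, cumsum))
  rowSums(cum[, -k, drop = FALSE]) / (k - 1)
}

#' Long-format rankogram data
#' @param P a `rank_matrix`.
#' @return data.frame with columns `treatment`, `rank`, `probability`,
#'   suitable for plotting rank curves.
#' @export
rankogram_data <- function(P) {
  data.frame(treatment = rep(rownames(P), ncol(P)),
             rank = rep(seq_len(ncol(P)), each = nrow(P)),
             probability = as.vector(unclass(P)),
             stringsAsFactors = FALSE)
}

#' @export
print.rank_matrix <- function(x, ...) {
  cat("Rank probabilities (", attr(x, "direction"),
      "; rank 1 = best):\n", sep = "")
  print(round(unclass(x), 3))
  invisible(x)
}
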