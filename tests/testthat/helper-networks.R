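# Shared fixture builders for the test suite.  Everything is generated
# in code; the only file fixture is the shipped evidence table.

pfs_network <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- load_trial_table(melnma_example("melanoma_pfs.csv"),
                                 outcome = "PFS")
    cache
  }
})

pfs_pooled <- function() merge_dose_arms(pfs_network(), "pool")

# a single two-arm trial network: treatment B vs A with given effect
two_node_network <- function(y, se, a = "A", b = "B", outcome = "PFS") {
  trts <- data.frame(id = c(a, b), label = c(a, b), reportable = TRUE,
                     stringsAsFactors = FALSE)
  arms <- data.frame(trial_id = rep("t1", 2), treatment = c(a, b),
                     n_enrolled = c(100, 100), stringsAsFactors = FALSE)
  ct <- data.frame(trial_id = "t1", baseline = a, treatment = b,
                   outcome = outcome, y = y, se = se,
                   stringsAsFactors = FALSE)
  evidence_network(trts, arms, ct, reference = a)
}

# triangle A-B, B-C, A-C (three two-arm trials)
triangle_network <- function(y_ab, y_bc, y_ac, se = 0.1) {
  trts <- data.frame(id = c("A", "B", "C"), label = c("A", "B", "C"),
                     reportable = TRUE, stringsAsFactors = FALSE)
  arms <- data.frame(trial_id = rep(c("t1", "t2", "t3"), each = 2),
                     treatment = c("A", "B", "B", "C", "A", "C"),
                     n_enrolled = 100, stringsAsFactors = FALSE)
  ct <- data.frame(trial_id = c("t1", "t2", "t3"),
                   baseline = c("A", "B", "A"),
                   treatment = c("B", "C", "C"),
                   outcome = "PFS", y = c(y_ab, y_bc, y_ac), se = se,
                   stringsAsFactors = FALSE)
  evidence_network(trts, arms, ct, reference = "A")
}

# a quick fixture fit at a reduced (but converging) schedule
quick_fit <- function(net = pfs_pooled(), effect = "fixed", seed = 100,
                      ...) {
  nma(net, "PFS", effect, chains = 2, burn_in = 4000, keep = 2500,
      thin = 4, seed = seed, ...)
}

# the Table 1 rows as (hr, lo, hi) for round-trip checks
table1_rows <- function() {
  tab <- utils::read.csv(melnma_example("melanoma_pfs.csv"),
                         stringsAsFactors = FALSE)
  tab <- tab[!is.na(tab$ci_low) & tab$ci_low != "", ]
  data.frame(hr = as.numeric(tab$hr), lo = as.numeric(tab$ci_low),
             hi = as.numeric(tab$ci_high))
}
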