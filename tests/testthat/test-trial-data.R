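test_that("se_from_ci inverts the normal CI construction", {
  # hand evaluation: log(0.73/0.45) / (2 * 1.959964)
  expect_equal(se_from_ci(0.45, 0.73),
               log(0.73 / 0.45) / (2 * qnorm(0.975)))
  expect_equal(se_from_ci(0.45, 0.73), 0.1234, tolerance = 1e-3)
  expect_equal(se_from_ci(0.31, 0.57), 0.1554, tolerance = 1e-3)
  # constructed interval of log-width 2z has unit standard error
  z <- qnorm(0.975)
  expect_equal(se_from_ci(0.2, 0.2 * exp(2 * z)), 1.0)
  # scale invariance in the ratio bounds
  for (k in c(0.01, 0.5, 7)) {
    expect_equal(se_from_ci(0.45 * k, 0.73 * k), se_from_ci(0.45, 0.73))
  }
  expect_error(se_from_ci(0.7, 0.5), "malformed")
  expect_error(se_from_ci(-1, 0.5), "positive")
})

test_that("every shipped CI round-trips through (y, se) to 3 decimals", {
  z <- qnorm(0.975)
  rows <- table1_rows()
  for (i in seq_len(nrow(rows))) {
    se <- se_from_ci(rows$lo[i], rows$hi[i])
    y <- (log(rows$lo[i]) + log(rows$hi[i])) / 2  # CI midpoint on logs
    expect_equal(exp(y - z * se), rows$lo[i], tolerance = 5e-4)
    expect_equal(exp(y + z * se), rows$hi[i], tolerance = 5e-4)
  }
})

test_that("the shipped evidence table ingests into the published network", {
  net <- pfs_network()
  expect_s3_class(net, "evidence_network")
  expect_length(unique(net$arms$trial_id), 12L)
  expect_equal(sum(net$treatments$reportable), 10L)
  expect_equal(nrow(net$treatments), 11L)   # + auxiliary gp100
  # only the 10 trials reporting HRs contribute contrasts
  expect_length(unique(net$contrasts$trial_id), 10L)
  expect_equal(nrow(net$contrasts), 14L)
  expect_true(is_connected(net, "PFS"))
  # the two HR-less trials still contribute arms
  expect_true(all(c("hersh2011", "weber2009") %in% net$arms$trial_id))
})

test_that("ingest rejects degenerate or malformed tables", {
  empty <- tempfile(fileext = ".csv")
  writeLines("trial_id,treatment,n,hr,ci_low,ci_high", empty)
  expect_error(load_trial_table(empty), "no trials")

  bad <- tempfile(fileext = ".csv")
  writeLines(c("trial_id,treatment,n,hr,ci_low,ci_high",
               "t1,NIV,100,0.8,0.9,0.7", "t1,CHE,100,1,,"), bad)
  expect_error(load_trial_table(bad), "malformed CI")

  unk <- tempfile(fileext = ".csv")
  writeLines(c("trial_id,treatment,n,hr,ci_low,ci_high",
               "t1,XYZ,100,0.8,0.6,0.9", "t1,CHE,100,1,,"), unk)
  expect_error(load_trial_table(unk), "unknown treatment")
})

test_that("a minimal two-arm table yields one trial, two nodes, one contrast", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("trial_id,treatment,n,hr,ci_low,ci_high",
               "t1,NIV,100,0.5,0.3,0.8", "t1,CHE,120,1,,"), f)
  net <- load_trial_table(f)
  expect_length(unique(net$arms$trial_id), 1L)
  expect_equal(nrow(net$contrasts), 1L)
  expect_equal(net$contrasts$baseline, "CHE")
  expect_equal(net$contrasts$y, log(0.5))
})

test_that("dose-arm pooling combines same-treatment contrasts by inverse variance", {
  net <- pfs_pooled()
  expect_equal(nrow(net$contrasts), 12L)
  # hand-checked inverse-variance mean of the two pembrolizumab doses
  ri <- net$contrasts[net$contrasts$trial_id == "ribas2015", ]
  expect_equal(nrow(ri), 1L)
  expect_equal(exp(ri$y), 0.5347, tolerance = 1e-3)
  # arms collapsed with summed enrolment
  expect_equal(net$arms$n_enrolled[net$arms$trial_id == "ribas2015" &
                                     net$arms$treatment == "PEM"], 361)
  # pooled se never exceeds the smaller input se
  raw <- pfs_network()$contrasts
  raw <- raw[raw$trial_id == "ribas2015", ]
  expect_lt(ri$se, min(raw$se))
})

test_that("pooling two identical contrasts divides the se by sqrt(2)", {
  trts <- melanoma_treatments()
  arms <- data.frame(trial_id = "t1", treatment = c("CHE", "PEM", "PEM"),
                     n_enrolled = c(100, 50, 50), stringsAsFactors = FALSE)
  ct <- data.frame(trial_id = "t1", baseline = "CHE",
                   treatment = c("PEM", "PEM"), outcome = "PFS",
                   y = c(-0.5, -0.5), se = c(0.2, 0.2),
                   stringsAsFactors = FALSE)
  net <- merge_dose_arms(evidence_network(trts, arms, ct), "pool")
  expect_equal(net$contrasts$y, -0.5)
  expect_equal(net$contrasts$se, 0.2 / sqrt(2))
})

test_that("keep_first drops later dose arms with a warning", {
  ws <- capture_warnings(net <- merge_dose_arms(pfs_network(),
                                                "keep_first"))
  expect_length(ws, 2L)        # one per trial with extra dose arms
  expect_match(ws, "keep_first", all = TRUE)
  ri <- net$contrasts[net$contrasts$trial_id == "ribas2015", ]
  expect_equal(exp(ri$y), 0.57)   # first-listed 2 mg/kg arm retained
  expect_identical(merge_dose_arms(pfs_network(), "keep_all_as_distinct"),
                   pfs_network())
})

test_that("auxiliary-node resolution follows the requested policy", {
  net <- pfs_network()
  # aux_node keeps gp100 in the likelihood but not among reportables
  kept <- resolve_auxiliary_nodes(net, "aux_node")
  expect_equal(nrow(kept$treatments), 11L)
  expect_equal(sum(kept$treatments$reportable), 10L)
  # rebasing differences the two gp100-anchored contrasts: 0.81/0.64
  reb <- resolve_auxiliary_nodes(net, "rebase_independent")
  expect_false("GP100" %in% c(reb$arms$treatment, reb$contrasts$baseline,
                              reb$contrasts$treatment))
  hodi <- reb$contrasts[reb$contrasts$trial_id == "hodi2010", ]
  expect_equal(nrow(hodi), 1L)
  expect_equal(hodi$baseline, "IPI")
  expect_equal(hodi$treatment, "IPI_GP100")
  expect_equal(exp(hodi$y), 0.81 / 0.64, tolerance = 1e-10)
  expect_equal(hodi$se,
               sqrt(se_from_ci(0.74, 0.92)^2 + se_from_ci(0.56, 0.78)^2))
  # no auxiliary treatments -> identity
  tno <- two_node_network(-0.3, 0.2)
  expect_identical(resolve_auxiliary_nodes(tno, "rebase_independent"), tno)
})

test_that("low-risk filtering restricts trials and guards connectivity", {
  net <- pfs_pooled()
  flags <- read_risk_flags(melnma_example("risk_flags_synthetic.csv"))
  expect_length(flags, 12L)
  low <- filter_low_risk(net, flags)
  expect_length(unique(low$arms$trial_id), 9L)
  expect_true(is_connected(low, "PFS"))
  # all low-risk -> identity on the trial roster
  all_ok <- setNames(rep(TRUE, 12), names(flags))
  expect_setequal(unique(filter_low_risk(net, all_ok)$arms$trial_id),
                  unique(net$arms$trial_id))
  # removing both trials that bridge the chemotherapy and ipilimumab
  # hubs splits the comparison graph
  cut <- all_ok
  cut[c("larkin2015", "robert2015p")] <- FALSE
  expect_error(filter_low_risk(net, cut), "disconnected")
  expect_error(filter_low_risk(net, flags[-1]), "missing")
})

test_that("load -> serialize -> load is lossless on the fixture", {
  net <- pfs_network()
  f <- tempfile(fileext = ".csv")
  write_trial_table(net, f)
  net2 <- load_trial_table(f, outcome = "PFS")
  expect_equal(net2$arms$trial_id, net$arms$trial_id)
  expect_equal(net2$arms$n_enrolled, net$arms$n_enrolled)
  o1 <- net$contrasts[order(net$contrasts$trial_id, net$contrasts$treatment,
                            net$contrasts$y), ]
  o2 <- net2$contrasts[order(net2$contrasts$trial_id, net2$contrasts$treatment,
                             net2$contrasts$y), ]
  expect_equal(o2$y, o1$y, tolerance = 1e-9)
  expect_equal(o2$se, o1$se, tolerance = 1e-9)
  expect_equal(o2$baseline, o1$baseline)
})

test_that("network validation enforces the arm and contrast invariants", {
  trts <- melanoma_treatments()
  arms <- data.frame(trial_id = "t1", treatment = c("CHE", "NIV"),
                     n_enrolled = c(100, 100), ae_any = c(10, 5),
                     ae_high = c(12, 2), stringsAsFactors = FALSE)
  ct <- data.frame(trial_id = character(), baseline = character(),
                   treatment = character(), outcome = character(),
                   y = numeric(), se = numeric(), stringsAsFactors = FALSE)
  expect_error(evidence_network(trts, arms, ct), "ae_high")
  arms$ae_high <- c(3, 2)
  expect_s3_class(evidence_network(trts, arms, ct), "evidence_network")
  bad_ct <- data.frame(trial_id = "t1", baseline = "CHE",
                       treatment = "NIV", outcome = "PFS", y = 0,
                       se = -1, stringsAsFactors = FALSE)
  expect_error(evidence_network(trts, arms, bad_ct), "standard error")
  dup <- rbind(bad_ct, bad_ct); dup$se <- 0.1
  expect_error(evidence_network(trts, arms, dup), "duplicate contrast")
})
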