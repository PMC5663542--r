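test_that("the design maps contrasts onto basic parameters correctly", {
  des <- build_design(pfs_pooled(), "PFS")
  # 9 reportable non-reference nodes with PFS data + auxiliary gp100
  expect_length(des$d_names, 9L)
  expect_false("IPI_BUD" %in% des$treatments)  # no PFS contrast
  expect_true("GP100" %in% des$treatments)
  expect_equal(des$treatments[1L], "CHE")

  two <- build_design(two_node_network(-0.5, 0.2), "PFS")
  expect_length(two$d_names, 1L)
  expect_equal(two$dat$c_t, 1L)
  expect_equal(two$dat$c_b, 0L)

  tri <- build_design(triangle_network(-0.2, -0.3, -0.5), "PFS")
  # the A-C contrast maps to d_C (minus d_A = 0 at the reference)
  i <- which(tri$contrasts$baseline == "A" & tri$contrasts$treatment == "C")
  expect_equal(tri$dat$c_t[i], match("C", tri$treatments) - 1L)
  expect_equal(tri$dat$c_b[i], 0L)
})

test_that("a disconnected network is rejected with its components", {
  trts <- data.frame(id = c("A", "B", "C", "D"), label = letters[1:4],
                     reportable = TRUE, stringsAsFactors = FALSE)
  arms <- data.frame(trial_id = rep(c("t1", "t2"), each = 2),
                     treatment = c("A", "B", "C", "D"), n_enrolled = 50,
                     stringsAsFactors = FALSE)
  ct <- data.frame(trial_id = c("t1", "t2"), baseline = c("A", "C"),
                   treatment = c("B", "D"), outcome = "PFS",
                   y = 0, se = 0.1, stringsAsFactors = FALSE)
  net <- evidence_network(trts, arms, ct, reference = "A")
  expect_error(build_design(net, "PFS"), "disconnected")
  expect_length(network_components(net, "PFS"), 2L)
})

test_that("the R and compiled log posteriors agree on random states", {
  set.seed(11)
  for (effect in c("fixed", "random")) {
    des <- build_design(pfs_pooled(), "PFS", effect)
    for (rep in 1:5) {
      d <- rnorm(des$dat$n_d)
      tau <- runif(1, 0.01, des$dat$tau_upper - 0.01)
      delta <- rnorm(des$dat$n_unit, 0, 0.5)
      lpR <- log_posterior(des, d, tau = if (effect == "random") tau,
                           delta = if (effect == "random") delta)
      lpC <- melnma:::mtc_log_post_cpp(des$dat, d,
                                       if (effect == "random") tau else 0,
                                       if (effect == "random") delta
                                         else numeric(),
                                       numeric())
      expect_equal(lpR, lpC, tolerance = 1e-10)
    }
  }
})

test_that("the log posterior has its closed form on a single contrast", {
  des <- build_design(two_node_network(0, 1), "PFS")
  # y = 0, se = 1, d = 0: normal log-kernel at zero plus the d prior
  expect_equal(log_posterior(des, 0),
               dnorm(0, 0, 1, log = TRUE) + dnorm(0, 0, 15, log = TRUE))
  # tau outside its prior support is -Inf, not an error
  desr <- build_design(two_node_network(0, 1), "PFS", "random")
  expect_identical(log_posterior(desr, 0, tau = 5, delta = 0), -Inf)
  expect_identical(log_posterior(desr, 0, tau = -1, delta = 0), -Inf)
})

test_that("the tau -> 0 limit of the random model recovers the fixed model", {
  net <- triangle_network(-0.2, -0.3, -0.5)
  desf <- build_design(net, "PFS", "fixed")
  desr <- build_design(net, "PFS", "random")
  d <- c(-0.25, -0.45)
  dv <- c(0, d)
  delta <- dv[desr$dat$u_t + 1L] - dv[desr$dat$u_b + 1L]
  # with delta pinned at the consistency values the likelihoods coincide
  devf <- melnma:::mtc_deviance_cpp(desf$dat, d, 0, numeric(), numeric())
  devr <- melnma:::mtc_deviance_cpp(desr$dat, d, 1e-6, delta, numeric())
  expect_equal(devf, devr, tolerance = 1e-10)
  # with tau ~ 0 the random log posterior differs from the fixed one
  # only by a constant (the RE normalizer): differences across d states
  # coincide
  d2 <- c(0.1, -0.7)
  delta2 <- c(0, d2)[desr$dat$u_t + 1L] - c(0, d2)[desr$dat$u_b + 1L]
  gap_fixed <- log_posterior(desf, d) - log_posterior(desf, d2)
  gap_rand <- log_posterior(desr, d, tau = 1e-8, delta = delta) -
    log_posterior(desr, d2, tau = 1e-8, delta = delta2)
  expect_equal(gap_rand, gap_fixed, tolerance = 1e-6)
})

test_that("the two-node posterior matches the conjugate normal oracle", {
  # vague prior: posterior of d is ~ N(y, se^2)
  fit <- nma(two_node_network(log(0.5), 0.2), "PFS", "fixed", chains = 2,
             burn_in = 2000, keep = 5000, thin = 2, seed = 5)
  d <- fit$draws[, "d[B]"]
  expect_equal(median(d), log(0.5), tolerance = 0.01)
  expect_equal(sd(d), 0.2, tolerance = 0.015)
  expect_true(fit$converged)
})

test_that("sampling is deterministic given the seed", {
  net <- pfs_pooled()
  f1 <- nma(net, "PFS", "fixed", chains = 2, burn_in = 500, keep = 200,
            thin = 2, seed = 42)
  f2 <- nma(net, "PFS", "fixed", chains = 2, burn_in = 500, keep = 200,
            thin = 2, seed = 42)
  expect_identical(f1$draws, f2$draws)
  f3 <- nma(net, "PFS", "fixed", chains = 2, burn_in = 500, keep = 200,
            thin = 2, seed = 43)
  expect_false(identical(f1$draws, f3$draws))
})

test_that("DIC behaves like an effective-parameter count", {
  fit <- quick_fit()
  expect_equal(fit$dic$DIC, fit$dic$Dbar + fit$dic$pD)
  # fixed-effect contrast model: pD close to the basic-parameter count
  expect_equal(fit$dic$pD, length(fit$design$d_names), tolerance = 0.75)
  # degenerate posterior: all draws equal -> pD = 0
  des <- fit$design
  pm <- colMeans(fit$draws)
  dev <- melnma:::mtc_deviance_cpp(des$dat, pm[des$d_names], 0,
                                   numeric(), numeric())
  expect_equal(dev - dev, 0)  # Dbar equals D(mean) when draws collapse
})

test_that("fixed beats random by DIC on homogeneous synthetic data", {
  # tau_true = 0: the simpler model should fit at least as well
  wins <- 0L
  for (s in 1:5) {
    net <- simulate_contrast_network(sim_truth(tau_true = 0, seed = 300 + s))
    ff <- suppressWarnings(nma(net, "PFS", "fixed", chains = 2,
                               burn_in = 2000, keep = 1000, thin = 2,
                               seed = s))
    fr <- suppressWarnings(nma(net, "PFS", "random", chains = 2,
                               burn_in = 2000, keep = 1000, thin = 2,
                               seed = s))
    if (ff$dic$DIC <= fr$dic$DIC + 3) wins <- wins + 1L
  }
  expect_gte(wins, 4L)
})

test_that("league tables are antisymmetric with a unit diagonal", {
  fit <- quick_fit()
  lt <- league_table(fit)
  expect_false("GP100" %in% rownames(lt$median))  # auxiliary excluded
  k <- nrow(lt$median)
  expect_equal(diag(lt$median), setNames(rep(1, k), rownames(lt$median)))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    expect_equal(lt$median[i, j], 1 / lt$median[j, i], tolerance = 1e-12)
    expect_equal(lt$lower[i, j], 1 / lt$upper[j, i], tolerance = 1e-12)
  }
  # medians multiply along any path: each entry is a monotone transform
  # of the same draw-wise sums
  bd <- basic_draws(fit)
  ab <- exp(median(bd[, "IPI"] - bd[, "NIV"]))
  bc <- exp(median(bd[, "NIV"] - bd[, "PEM"]))
  ac <- exp(median(bd[, "IPI"] - bd[, "PEM"]))
  expect_equal(log(ab) + log(bc), log(ac), tolerance = 0.05)
  # draw-wise consistency is exact for every triple
  expect_equal((bd[, "IPI"] - bd[, "NIV"]) + (bd[, "NIV"] - bd[, "PEM"]),
               bd[, "IPI"] - bd[, "PEM"], tolerance = 1e-12)
})

test_that("the league table is invariant to the reference treatment", {
  f1 <- quick_fit(seed = 61)
  f2 <- quick_fit(seed = 62, reference = "IPI")
  l1 <- league_table(f1); l2 <- league_table(f2)
  common <- intersect(rownames(l1$median), rownames(l2$median))
  for (a in c("IPI_NIV", "NIV", "PEM")) for (b in c("IPI", "TRE")) {
    expect_equal(log(l1$median[b, a]), log(l2$median[b, a]),
                 tolerance = 0.03)
  }
})

test_that("vague priors do not drive the fixture estimates", {
  f1 <- quick_fit(seed = 71)
  f2 <- quick_fit(seed = 72, prior_sd_d = 150)
  d1 <- coef(f1); d2 <- coef(f2)
  expect_lt(max(abs(d1 - d2)), 0.03)
})
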