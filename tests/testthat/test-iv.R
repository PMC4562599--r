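pr_default <- voltage_protocol()

make_decay_trace <- function(I_o = -80, tau = 50, I_inf = -20,
                             protocol = pr_default, noise_sd = 0) {
  t <- seq(0, protocol$baseline_ms + protocol$agonist_ms,
           by = protocol$sample_ms)
  s <- t - protocol$baseline_ms
  cur <- ifelse(s < 0, 0, I_o * exp(-s / tau) + I_inf)
  if (noise_sd > 0) cur <- cur + stats::rnorm(length(cur), sd = noise_sd)
  data.frame(time_ms = t, current = cur)
}

test_that("peak current returns the signed in-window extremum", {
  tr <- make_decay_trace(-80, 50, -20)
  expect_equal(peak_current(tr, pr_default), -100)  # I_o + I_inf at onset
  # constructed mid-window extremum, found by brute-force scan
  t <- seq(0, 300, 1)
  cur <- -sin(pi * pmax(t - 50, 0) / 250) * 40
  tr2 <- data.frame(time_ms = t, current = cur)
  w <- t >= 50 & t <= 300
  expect_equal(peak_current(tr2, pr_default), cur[w][which.max(abs(cur[w]))])
  # nonzero baseline is subtracted before taking the extremum
  tr3 <- tr
  tr3$current <- tr3$current + 7
  expect_equal(peak_current(tr3, pr_default), -100)
  # window with no samples errors
  short <- data.frame(time_ms = 0:10, current = rep(0, 11))
  expect_error(peak_current(short, voltage_protocol(baseline_ms = 500)),
               "no samples")
})

test_that("single-exponential decay fit recovers known parameters", {
  fit <- fit_decay(make_decay_trace(-80, 50, -20), pr_default)
  expect_equal(fit$I_o, -80, tolerance = 0.01)
  expect_equal(fit$tau_d, 50, tolerance = 0.01)
  expect_equal(fit$I_inf, -20, tolerance = 0.01)
  expect_lt(fit$rmse, 1e-6)
  # round trip through the simulator's kinetics
  ch <- anion_channel(18.8, scale = 500)
  tr <- simulate_trace(ch, -60, REG[["1NaCl"]], REG$I2, pr_default,
                       kinetics_spec(tau_d_ms = 50, plateau_fraction = 0.25))
  fit2 <- fit_decay(tr, pr_default)
  peak <- peak_current(tr, pr_default)
  expect_equal(fit2$tau_d, 50, tolerance = 0.01)
  expect_equal(fit2$I_inf / peak, 0.25, tolerance = 0.01)
})

test_that("decay fit tolerates noise and rejects degenerate traces", {
  set.seed(8)
  fit <- fit_decay(make_decay_trace(-80, 50, -20, noise_sd = 1), pr_default)
  expect_lt(abs(fit$tau_d - 50) / 50, 0.10)
  flat <- data.frame(time_ms = 0:300, current = rep(-5, 301))
  expect_error(fit_decay(flat, pr_default), "unidentifiable")
  tiny <- data.frame(time_ms = seq(0, 55, 1),
                     current = c(rep(0, 50), -(6:1)))
  expect_error(fit_decay(tiny, pr_default), "at least 10 samples")
})

test_that("replicate QC implements the 80% pairwise-difference rule", {
  ok <- qc_replicates(c(-100, -95, -90))
  expect_true(ok$keep)
  expect_equal(ok$max_rel_diff, 0.10)      # hand arithmetic: 10/100
  bad <- qc_replicates(c(-100, -10))
  expect_false(bad$keep)                    # 90/100 = 90% > 80%
  expect_equal(bad$max_rel_diff, 0.90)
  # exactly at the threshold: the rule fires only above 80%
  expect_true(qc_replicates(c(-100, -20))$keep)
  expect_false(qc_replicates(c(-100, -19.9))$keep)
  single <- qc_replicates(-50)
  expect_true(single$keep)
  expect_match(single$flags, "single replicate")
  none <- qc_replicates(c(0, 0, 0))
  expect_false(none$keep)
  expect_identical(none$reason, "no response")
})

test_that("replicate QC is permutation invariant", {
  set.seed(21)
  for (i in 1:20) {
    peaks <- stats::rnorm(5, mean = -60, sd = 30)
    base <- qc_replicates(peaks)
    perm <- qc_replicates(sample(peaks))
    expect_identical(perm$keep, base$keep)
    expect_equal(perm$max_rel_diff, base$max_rel_diff)
  }
})

test_that("averaging and normalization behave under scaling and repetition", {
  peaks <- expand.grid(holding_mV = c(-40, 0, 40), replicate_id = 1:3)
  peaks$peak <- with(peaks, holding_mV * 2 + replicate_id)
  iv <- average_normalize(peaks, n_avg = 3)
  hand <- tapply(peaks$peak, peaks$holding_mV, mean)
  expect_equal(iv$mean_peak, as.numeric(hand))
  expect_equal(attr(iv, "I_max"), max(abs(hand)))
  # identical replicates: averaging is a no-op
  eq <- peaks; eq$peak <- eq$holding_mV * 2
  iv_eq <- average_normalize(eq, 3)
  expect_equal(iv_eq$mean_peak, unique(eq$peak)[order(unique(eq$holding_mV))])
  # positive rescaling leaves the normalized curve unchanged
  sc <- peaks; sc$peak <- sc$peak * 2
  expect_equal(average_normalize(sc, 3)$norm_peak, iv$norm_peak)
  # fewer replicates than requested are used and flagged
  few <- peaks[peaks$replicate_id == 1, ]
  iv_few <- average_normalize(few, 3)
  expect_match(attr(iv_few, "flags")[1], "only 1 replicate")
  expect_equal(iv_few$n_used, rep(1L, 3))
})

test_that("E_rev interpolation: antisymmetric pair, invariance, errors", {
  iv <- data.frame(holding_mV = c(-20, 0), mean_peak = c(-5, 5))
  expect_equal(estimate_erev(iv)$value, -10)
  iv2 <- iv; iv2$mean_peak <- iv2$mean_peak * 17
  expect_equal(estimate_erev(iv2)$value, -10)  # scale invariance
  same_sign <- data.frame(holding_mV = c(-20, 0, 20),
                          mean_peak = c(1, 2, 3))
  expect_error(estimate_erev(same_sign), "no zero crossing")
})

test_that("interpolated E_rev matches the closed form on noiseless GHK I-V", {
  ch <- anion_channel(18.8, scale = 1)
  pr <- voltage_protocol()
  for (nm in c("1NaCl", "0.5NaCl", "0.25NaCl")) {
    sol <- REG[[nm]]
    closed <- ghk_erev_multi(ch, sol, REG$I2)$value
    iv <- data.frame(
      holding_mV = pr$holding_mV,
      mean_peak = ghk_current_density(ch, pr$holding_mV, sol, REG$I2))
    est <- estimate_erev(iv)
    expect_lt(abs(est$value - closed), 1.5)
    # quadratic refinement should do at least as well here
    est_q <- estimate_erev(iv, method = "quad")
    expect_lt(abs(est_q$value - closed), 1.0)
  }
})

test_that("full-chain analysis recovers analytic E_rev on noiseless sets", {
  ch <- anion_channel(18.8)
  conds <- list(
    `1NaCl` = list(sol_out = REG[["1NaCl"]], sol_in = REG$I2),
    `0.25NaCl` = list(sol_out = REG[["0.25NaCl"]], sol_in = REG$I2))
  rs <- simulate_experiment(ch, conds, noise = noise_spec(0, 0, 1),
                            n_replicates = 3)
  res <- analyze_recording_set(rs)
  expect_length(res$discarded, 0)
  for (nm in names(conds)) {
    analytic <- ghk_erev_multi(ch, conds[[nm]]$sol_out, REG$I2)$value
    expect_lt(abs(res$erev[[nm]]$value - analytic), 1.5)
  }
})

test_that("an outlier replicate discards the whole experiment with a reason", {
  ch <- anion_channel(18.8)
  conds <- list(`0.5NaCl` = list(sol_out = REG[["0.5NaCl"]], sol_in = REG$I2))
  rs <- simulate_experiment(ch, conds, noise = noise_spec(0, 0, 1),
                            n_replicates = 3)
  # shrink replicate 3 to 5% of its amplitude: 95% pairwise difference
  sel <- rs$replicate_id == 3
  rs$current_pA[sel] <- rs$current_pA[sel] * 0.05
  res <- analyze_recording_set(rs)
  expect_named(res$discarded, "0.5NaCl")
  expect_match(res$discarded[["0.5NaCl"]], "relative difference")
  expect_length(res$iv_curves, 0)
})
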