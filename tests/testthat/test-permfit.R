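EXPT <- default_dilution_experiment()

test_that("dilution curves difference against the reference condition", {
  erev <- list(`1NaCl` = erev_estimate(-0.2, "interpolated"),
               `0.5NaCl` = erev_estimate(15.1, "interpolated"),
               `0.25NaCl` = erev_estimate(29.4, "interpolated"))
  curve <- build_dilution_curve(EXPT, erev)
  expect_equal(curve$dErev_mV[curve$condition_id == "1NaCl"], 0)
  expect_equal(curve$dErev_mV[curve$condition_id == "0.25NaCl"],
               29.4 - (-0.2))
  expect_equal(curve$aCl_o, c(149, 76.5, 40.25))
  expect_error(build_dilution_curve(EXPT, erev[-1]), "1NaCl")
})

test_that("the activity model moves x coordinates but not the shifts", {
  erev <- list(`1NaCl` = 0, `0.5NaCl` = 15, `0.25NaCl` = 29)
  cu <- build_dilution_curve(EXPT, erev, activity_model("unity"))
  cd <- build_dilution_curve(EXPT, erev, activity_model("davies"))
  expect_equal(cd$dErev_mV, cu$dErev_mV)
  expect_true(all(cd$aCl_o < cu$aCl_o))
})

test_that("noiseless analytic curves sit on the GHK closed form", {
  r <- 18.8
  curve <- analytic_dilution_curve(EXPT, r)
  a_cl_i <- ion_total(EXPT$internal, "Cl")
  a_na_i <- ion_total(EXPT$internal, "Na")
  for (i in seq_len(nrow(curve))) {
    sol <- EXPT$externals[[curve$condition_id[i]]]
    direct <- ghk_erev_two_ion(r, ion_total(sol, "Na"), a_na_i,
                               ion_total(sol, "Cl"), a_cl_i) -
      ghk_erev_two_ion(r, 145, a_na_i, 149, a_cl_i)
    expect_equal(curve$dErev_mV[i], direct, tolerance = 1e-12)
  }
})

test_that("noise-free fits recover the generating ratio to 1e-4 relative", {
  for (r in c(0.01, 0.1, 0.19, 1, 18.8, 100)) {
    fit <- fit_pcl_pna(EXPT, analytic_dilution_curve(EXPT, r), n_boot = 0)
    expect_lt(abs(fit$p_cl_over_p_na - r) / r, 1e-4)
  }
})

test_that("Nernst-limit curves drive the fit to the extremes", {
  fit_inf <- fit_pcl_pna(EXPT, analytic_dilution_curve(EXPT, Inf), n_boot = 0)
  expect_gt(fit_inf$p_cl_over_p_na, 1e3)
  expect_identical(fit_inf$classification, "anion_selective")
  fit_zero <- fit_pcl_pna(EXPT, analytic_dilution_curve(EXPT, 0), n_boot = 0)
  expect_lt(fit_zero$p_cl_over_p_na, 1e-3)
  expect_identical(fit_zero$classification, "cation_selective")
  # the reported hypothetical limit curves bracket any finite-ratio curve
  fit <- fit_pcl_pna(EXPT, analytic_dilution_curve(EXPT, 18.8), n_boot = 0)
  dil <- fit$curve$condition_id != "1NaCl"
  expect_true(all(fit$curve$dErev_mV[dil] < fit$limits$dErev_inf[dil]))
  expect_true(all(fit$curve$dErev_mV[dil] > fit$limits$dErev_zero[dil]))
})

test_that("the objective is unimodal in log-ratio on noiseless data", {
  curve <- analytic_dilution_curve(EXPT, 18.8)
  obs <- curve$dErev_mV
  grid <- seq(log(1e-4), log(1e4), length.out = 161)
  sse <- vapply(grid, function(lr) {
    pred <- analytic_dilution_curve(EXPT, exp(lr))$dErev_mV
    sum((obs - pred)^2)
  }, numeric(1))
  d <- diff(sse)
  # strictly decreasing then increasing: exactly one sign change in the slope
  expect_identical(sum(diff(sign(d[d != 0])) != 0), 1L)
  expect_equal(grid[which.min(sse)], log(18.8), tolerance = 0.1)
})

test_that("the fitted ratio ignores the redundant reference point", {
  curve <- analytic_dilution_curve(EXPT, 5.5)
  with_ref <- fit_pcl_pna(EXPT, curve, n_boot = 0)$p_cl_over_p_na
  without_ref <- fit_pcl_pna(EXPT, curve[curve$condition_id != "1NaCl", ],
                             n_boot = 0)$p_cl_over_p_na
  expect_equal(with_ref, without_ref, tolerance = 1e-6)
})

test_that("selectivity classification thresholds", {
  expect_identical(classify_selectivity(18.8), "anion_selective")
  expect_identical(classify_selectivity(0.19), "cation_selective")
  expect_identical(classify_selectivity(1.0), "nonselective")
  expect_identical(classify_selectivity(5.01), "anion_selective")
  expect_identical(classify_selectivity(0.49), "cation_selective")
})

test_that("noisy recovery: median fitted log-ratio stays near the truth", {
  rec <- recovery_study(truths = c(0.19, 18.8), n_experiments = 5,
                        sd_mV = 1.5, n_seeds = 25, seed = 17)
  med <- tapply(rec$log_err, rec$truth, stats::median)
  expect_true(all(abs(med) < 0.2))
})

test_that("bootstrap CIs cover the truth in a seeded simulation", {
  cov <- recovery_study(truths = 18.8, n_experiments = 5, sd_mV = 1.5,
                        n_seeds = 30, seed = 23, n_boot = 200)
  expect_true(all(cov$ci_low <= cov$ratio_hat & cov$ratio_hat <= cov$ci_high))
  expect_gte(mean(cov$covered), 0.85)
})

test_that("shift analysis: identity, constructed offset, analytic directions", {
  same <- shift_analysis(c(-20, -21, -19, -20.5), c(-20, -21, -19, -20.5),
                         seed = 3)
  expect_equal(same$delta_mV, 0)
  expect_identical(same$direction, "none")
  set.seed(31)
  a <- stats::rnorm(6, -20, 1)
  b <- a + 10
  off <- shift_analysis(a, b, seed = 4)
  expect_equal(off$delta_mV, 10, tolerance = 1e-9)
  expect_identical(off$direction, "positive")
  expect_true(off$ci_low > 0)
  # single noisy estimates cannot determine a direction
  expect_identical(shift_analysis(-20, -10)$direction, "undetermined")
  # single analytic values can
  expect_identical(shift_analysis(-20, -10, analytic = TRUE)$direction,
                   "positive")
})

test_that("K+/Ca2+ swaps mirror a monovalent-cation channel's physiology", {
  res <- run_shift_study(cation_channel())
  # raising external K+ (ES2 -> ES4) depolarizes E_rev
  expect_identical(res$shifts$high_K$direction, "positive")
  expect_gt(res$shifts$high_K$delta_mV, 10)
  # raising external Ca2+ (ES2 -> ES5) does ~nothing when P_Ca = 0
  expect_lt(abs(res$shifts$high_Ca$delta_mV), 2)
  # but a Ca-permeant channel would shift positive
  ca_perm <- channel_model(c(Na = 1, K = 1, Ca = 1))
  res_ca <- run_shift_study(ca_perm)
  expect_gt(res_ca$shifts$high_Ca$delta_mV, 2)
})

test_that("fit results serialize to JSON", {
  fit <- fit_pcl_pna(EXPT, analytic_dilution_curve(EXPT, 18.8),
                     n_boot = 50, boot_seed = 2)
  path <- withr::local_tempfile(fileext = ".json")
  fit_to_json(fit, path)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(doc$p_cl_over_p_na, fit$p_cl_over_p_na, tolerance = 1e-9)
  expect_identical(doc$classification, "anion_selective")
  expect_equal(nrow(doc$curve), 3)
})
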