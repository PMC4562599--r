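test_that("Nernst potential: symmetry, magnitude, charge antisymmetry", {
  expect_equal(nernst(100, 100, 1, ctx22), 0)
  # (RT/F) ln 2 at 295.15 K, frozen from direct evaluation of the formula
  expect_equal(nernst(145, 72.5, 1, ctx22), 17.62955, tolerance = 1e-6)
  expect_equal(nernst(145, 72.5, -1, ctx22), -nernst(145, 72.5, 1, ctx22))
  expect_equal(nernst(145, 72.5, 2, ctx22), nernst(145, 72.5, 1, ctx22) / 2)
  expect_error(nernst(0, 100, 1, ctx22), "positive")
  expect_error(nernst(100, 100, 0, ctx22), "neutral")
  # RT/F is computed from constants, ~25.4 mV at 22 C
  expect_equal(rtf_mV(ctx22), 25.43406, tolerance = 1e-5)
})

test_that("two-ion GHK reversal potential: limits and frozen value", {
  # symmetric solutions give 0 mV for any ratio
  for (r in c(0, 0.19, 1, 18.8, 1e6)) {
    expect_equal(ghk_erev_two_ion(r, 145, 145, 149, 149, ctx22), 0)
  }
  # p_ratio = 0 reduces to the Na Nernst potential
  expect_equal(ghk_erev_two_ion(0, 145, 72.5, 10, 20, ctx22),
               nernst(145, 72.5, 1, ctx22))
  # p_ratio -> Inf approaches the Cl Nernst potential
  expect_equal(ghk_erev_two_ion(Inf, 145, 72.5, 10, 20, ctx22),
               nernst(10, 20, -1, ctx22))
  expect_equal(ghk_erev_two_ion(1e9, 145, 72.5, 10, 20, ctx22),
               nernst(10, 20, -1, ctx22), tolerance = 1e-6)
  # frozen from independent evaluation of the printed equation
  expect_equal(ghk_erev_two_ion(18.8, 72.5, 145, 72.5, 145, ctx22),
               15.72586, tolerance = 1e-6)
  expect_error(ghk_erev_two_ion(-1, 1, 1, 1, 1, ctx22), ">= 0")
  expect_error(ghk_erev_two_ion(1, 0, 1, 1, 1, ctx22), "positive")
})

test_that("two-ion E_rev is monotone in the ratio between the Nernst limits", {
  # dilution geometry: outside diluted relative to inside
  ratios <- 10^seq(-3, 3, length.out = 25)
  e <- vapply(ratios, ghk_erev_two_ion, numeric(1),
              aNa_o = 72.5, aNa_i = 145, aCl_o = 76.5, aCl_i = 149,
              ctx = ctx22)
  expect_true(all(diff(e) > 0))
  expect_gt(min(e), nernst(72.5, 145, 1, ctx22))
  expect_lt(max(e), nernst(76.5, 149, -1, ctx22))
})

test_that("GHK current density vanishes at the reversal potential", {
  ch <- anion_channel(18.8, scale = 1)
  erev <- ghk_erev_two_ion(18.8, 72.5, 145, 76.5, 149, ctx22)
  i <- ghk_current_density(ch, erev, REG[["0.5NaCl"]], REG$I2, ctx = ctx22)
  amp <- ghk_current_density(ch, erev + 50, REG[["0.5NaCl"]], REG$I2,
                             ctx = ctx22)
  expect_lt(abs(i / amp), 1e-9)
  # symmetric solutions at V = 0: equilibrium, zero current
  expect_equal(
    ghk_current_density(ch, 0, REG[["1NaCl"]], REG$I2, ctx = ctx22), 0,
    tolerance = 1e-12)
})

test_that("GHK current is continuous across the V = 0 series patch", {
  ch <- channel_model(c(Na = 1, Cl = 18.8, Ca = 0.1))
  # the series branch engages below |u| = 1e-4, i.e. |V| ~ 2.5e-3 mV
  v_lo <- 2.4e-3
  v_hi <- 2.6e-3
  for (v in c(v_lo, v_hi)) {
    a <- ghk_current_density(ch, v, REG[["0.5NaCl"]], REG$I2, ctx = ctx22)
    b <- ghk_current_density(ch, v + 1e-9, REG[["0.5NaCl"]], REG$I2,
                             ctx = ctx22)
    expect_equal(a, b, tolerance = 1e-9)
  }
  v <- seq(-0.01, 0.01, length.out = 401)
  i <- ghk_current_density(ch, v, REG[["0.5NaCl"]], REG$I2, ctx = ctx22)
  expect_true(all(diff(i) > 0))  # smooth and increasing through 0
})

test_that("single permeant ion: current zero crossing equals Nernst", {
  ch_k <- channel_model(c(K = 1))
  est <- ghk_erev_multi(ch_k, REG$ES4, REG$I1, ctx = ctx22)
  expect_equal(est$value,
               nernst(ion_total(REG$ES4, "K"), ion_total(REG$I1, "K"), 1,
                      ctx22),
               tolerance = 1e-6)
  expect_identical(est$method, "root_find")
})

test_that("root-find E_rev matches the closed form on random monovalent draws", {
  set.seed(42)
  for (i in 1:100) {
    r <- 10^stats::runif(1, -2, 2)
    na_o <- stats::runif(1, 5, 200); na_i <- stats::runif(1, 5, 200)
    cl_o <- stats::runif(1, 5, 200); cl_i <- stats::runif(1, 5, 200)
    sol_o <- build_solution("o", "extracellular", list(
      salt_component("NaCl", min(na_o, cl_o)),
      if (na_o > cl_o) salt_component("Na-gluconate", na_o - cl_o)
      else salt_component("NMDG-Cl", cl_o - na_o)))
    sol_i <- build_solution("i", "intracellular", list(
      salt_component("NaCl", min(na_i, cl_i)),
      if (na_i > cl_i) salt_component("Na-gluconate", na_i - cl_i)
      else salt_component("NMDG-Cl", cl_i - na_i)))
    closed <- ghk_erev_two_ion(r, na_o, na_i, cl_o, cl_i, ctx22)
    rooted <- ghk_erev_multi(channel_model(c(Na = 1, Cl = r)),
                             sol_o, sol_i, ctx = ctx22)$value
    expect_lt(abs(closed - rooted), 0.01)
  }
})

test_that("E_rev is invariant under joint permeability rescaling; currents scale", {
  v <- c(-60, -20, 30)
  for (c_scale in c(0.1, 3, 250)) {
    p1 <- channel_model(c(Na = 1, Cl = 18.8))
    p2 <- channel_model(c(Na = 1, Cl = 18.8) * c_scale)
    expect_equal(ghk_erev_multi(p2, REG[["0.25NaCl"]], REG$I2,
                                ctx = ctx22)$value,
                 ghk_erev_multi(p1, REG[["0.25NaCl"]], REG$I2,
                                ctx = ctx22)$value,
                 tolerance = 1e-7)
    expect_equal(
      ghk_current_density(p2, v, REG[["0.25NaCl"]], REG$I2, ctx = ctx22),
      c_scale *
        ghk_current_density(p1, v, REG[["0.25NaCl"]], REG$I2, ctx = ctx22))
  }
})

test_that("impermeant additions leave the reversal potential unchanged", {
  ch <- anion_channel(18.8)
  base <- ghk_erev_multi(ch, REG[["0.5NaCl"]], REG$I2, ctx = ctx22)$value
  spiked <- build_solution("spiked", "extracellular", c(
    REG[["0.5NaCl"]]$components,
    list(salt_component("sucrose", 150), salt_component("glucose", 20))))
  expect_equal(ghk_erev_multi(ch, spiked, REG$I2, ctx = ctx22)$value, base)
})

test_that("no zero crossing in the bracket raises an informative error", {
  # pure Na+ channel with no internal Na+: current is inward everywhere,
  # so no reversal exists inside the physiological bracket
  ch <- channel_model(c(Na = 1))
  expect_error(ghk_erev_multi(ch, REG$ES1, REG$I1, ctx = ctx22),
               "no zero-current crossing")
})

test_that("channel models serialize through YAML", {
  path <- withr::local_tempfile(fileext = ".yml")
  ch <- channel_model(c(Na = 1, K = 1, Cl = 0.19), conductance_scale = 42)
  channel_to_yaml(ch, path)
  back <- channel_from_yaml(path)
  expect_equal(back$permeabilities, ch$permeabilities)
  expect_equal(back$conductance_scale, 42)
})
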