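# Spectroelectrochemistry: baseline, SHE referencing, the Nernstian
# sigmoid, limb normalization and the joint midpoint fit.

test_that("baseline correction zeroes the 700 nm reference", {
  sp <- data.frame(wavelength = seq(350, 700, 10), absorbance = 0.3)
  bc <- baseline_correct(sp)
  expect_true(all(bc$absorbance == 0))
  # already zero at 700 -> unchanged
  sp2 <- data.frame(wavelength = c(420, 700), absorbance = c(0.8, 0))
  expect_equal(baseline_correct(sp2)$absorbance, c(0.8, 0))
  # constant offset removed exactly
  sp3 <- data.frame(wavelength = seq(400, 700, 50),
                    absorbance = sin(seq(400, 700, 50) / 40))
  off <- sp3; off$absorbance <- off$absorbance + 0.12
  expect_equal(baseline_correct(off)$absorbance,
               baseline_correct(sp3)$absorbance, tolerance = 1e-12)
  # missing reference wavelength warns and uses the nearest
  sp4 <- data.frame(wavelength = c(400, 690), absorbance = c(1, 0.2))
  expect_warning(bc4 <- baseline_correct(sp4), "nearest")
  expect_equal(bc4$absorbance, c(0.8, 0))
})

test_that("SHE referencing adds the electrode offset once", {
  expect_equal(correct_reference(0, 0), 200)
  expect_equal(correct_reference(100, -50), 250)
  # applying the correction twice is not idempotent - guard against it
  once <- correct_reference(0, 0)
  twice <- correct_reference(once, 0)
  expect_equal(twice - once, 200)
})

test_that("the Nernstian sigmoid has the right midpoint, asymptotes and width", {
  expect_equal(nernst_absorbance(250, E_m = 250, A_ox = 0.1, a = 0.6), 0.4)
  # oxidized asymptote at high potential
  expect_lt(nernst_absorbance(250 + 500, E_m = 250, A_ox = 0, a = 1), 1e-8)
  expect_equal(nernst_absorbance(250 - 500, E_m = 250, A_ox = 0, a = 1), 1,
               tolerance = 1e-8)
  # 10-90% transition width = 2 ln(9) RT/(nF) ~ 110.9 mV at n = 1, 293 K
  width_theory <- 2 * log(9) * 8.3145 * 293 / 96485.34 * 1000
  expect_equal(width_theory, 110.9, tolerance = 1e-3)
  E10 <- uniroot(function(E) nernst_absorbance(E, 0) - 0.1, c(0, 200))$root
  E90 <- uniroot(function(E) nernst_absorbance(E, 0) - 0.9, c(-200, 0))$root
  expect_equal(E10 - E90, width_theory, tolerance = 1e-6)
  # monotone decreasing in E
  E <- seq(-300, 300, 10)
  expect_true(all(diff(nernst_absorbance(E, 0)) < 0))
})

test_that("limb normalization is affine-invariant and removes hysteresis", {
  tc <- simulate_titration(250, noise_sd = 0, hysteresis_scale = 1,
                           hysteresis_offset = 0, n_experiments = 1, seed = 1)
  # a clean limb already spanning [0, 1] is unchanged
  nl <- normalize_limbs(tc)
  expect_equal(nl$A420, tc$A420, tolerance = 1e-7)
  # affine distortion x2 + 0.5 normalizes back to the same limb
  tc2 <- tc; tc2$A420 <- 2 * tc$A420 + 0.5
  expect_equal(normalize_limbs(tc2)$A420, nl$A420, tolerance = 1e-7)
  # hysteresis pair overlays after normalization
  th <- simulate_titration(250, noise_sd = 0, hysteresis_scale = 0.8,
                           hysteresis_offset = 0.15, n_experiments = 1,
                           seed = 1)
  nh <- normalize_limbs(th)
  ox <- nh[nh$limb == "oxidative", ]
  red <- nh[nh$limb == "reductive", ]
  red <- red[match(ox$E_mV, red$E_mV), ]
  expect_equal(ox$A420, red$A420, tolerance = 1e-6)
  # degenerate flat limb errors
  flat <- tc; flat$A420 <- 0.5
  expect_error(normalize_limbs(flat), "degenerate")
  # observed-extremes variant rescales to [0, 1] when the potential window
  # actually reaches both plateaus
  tw <- simulate_titration(0, noise_sd = 0, hysteresis_scale = 0.8,
                           hysteresis_offset = 0.15, n_experiments = 1,
                           seed = 1)
  no <- normalize_limbs(tw, method = "observed")
  expect_equal(range(no$A420), c(0, 1), tolerance = 0.01)
})

test_that("noiseless Nernst fits recover the midpoint essentially exactly", {
  for (Em in c(244, 268, 272)) {
    tc <- simulate_titration(Em, noise_sd = 0, hysteresis_scale = 1,
                             hysteresis_offset = 0, n_experiments = 1,
                             seed = 3)
    f <- fit_nernst(normalize_limbs(tc))
    expect_equal(f$E_m, Em, tolerance = 1e-6)
    expect_lt(f$rss, 1e-12)
  }
})

test_that("fitted midpoints shift exactly with a potential shift", {
  tc <- simulate_titration(268, noise_sd = 0.02, n_experiments = 2,
                           seed = c(11, 12))
  f0 <- fit_nernst(normalize_limbs(tc))
  tc_shift <- tc; tc_shift$E_mV <- tc$E_mV + 37
  f1 <- fit_nernst(normalize_limbs(tc_shift))
  expect_equal(f1$E_m - f0$E_m, 37, tolerance = 1e-6)
  # and are invariant to pre-normalization scale/offset
  tc_aff <- tc; tc_aff$A420 <- 3 * tc$A420 - 0.2
  f2 <- fit_nernst(normalize_limbs(tc_aff))
  expect_equal(f2$E_m, f0$E_m, tolerance = 1e-6)
})

test_that("fixing the wrong electron count inflates the residuals", {
  tc <- simulate_titration(260, noise_sd = 0.01, n_experiments = 2,
                           seed = c(21, 22))
  nl <- normalize_limbs(tc)
  f1 <- fit_nernst(nl, n = 1)
  f2 <- fit_nernst(nl, n = 2)
  expect_gt(f2$rss, 2 * f1$rss)
})

test_that("the midpoint estimator is unbiased over seeds", {
  ems <- vapply(1:40, function(s) {
    tc <- simulate_titration(268, noise_sd = 0.02, n_experiments = 1,
                             seed = 1000 + s)
    fit_nernst(normalize_limbs(tc))$E_m
  }, numeric(1))
  expect_lt(abs(mean(ems) - 268), 1)
  # SE shrinks roughly as 1/sqrt(points): a denser ladder tightens the fit
  tc_dense <- simulate_titration(268, noise_sd = 0.02, n_experiments = 1,
                                 E_grid = seq(-300, 300, length.out = 100),
                                 seed = 77)
  tc_sparse <- simulate_titration(268, noise_sd = 0.02, n_experiments = 1,
                                  seed = 77)
  expect_lt(fit_nernst(normalize_limbs(tc_dense))$se_E_m,
            fit_nernst(normalize_limbs(tc_sparse))$se_E_m)
})
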