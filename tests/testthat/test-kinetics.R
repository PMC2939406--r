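test_that("glycation curve accumulates linearly from zero to twice steady", {
  cv <- glycation_curve(mpg = 137)
  expect_equal(curve_value(cv, 0), 0)
  expect_equal(curve_value(cv, 4), 2 * (137 / 35.6 + 2.17))   # ~12.04
  expect_equal(round_half_out(curve_value(cv, 4)), 12)
  expect_equal(round_half_out(curve_value(cv, 2)), 6)
  cv244 <- glycation_curve(mpg = 244)
  expect_equal(curve_value(cv244, 2), 244 / 35.6 + 2.17)      # ~9.02
  # linear in age
  m <- seq(0, 4, by = 0.5)
  expect_equal(curve_value(cv, m), cv$steady_hba1c * m / 2)
  expect_error(curve_value(cv, 4.5), "lifespan")
  expect_error(curve_value(cv, -0.1), "lifespan")
})

test_that("steady cohort mean is the arithmetic mean of curve extremes", {
  for (mpg in c(101, 137, 244, 350)) {
    cv <- glycation_curve(mpg = mpg)
    expect_equal(cohort_mean_steady(cv), curve_value(cv, 4) / 2)
    expect_equal(cohort_mean_steady(cv), hba1c_from_mpg(mpg))
  }
  # curves can equally be anchored in HbA1c space
  cv <- glycation_curve(steady_hba1c = 9)
  expect_equal(cohort_mean_steady(cv), 9)
  expect_equal(cv$mpg, mpg_from_hba1c(9))
})

test_that("scenario construction keeps HbA1c and MPG spaces consistent", {
  sc <- mixture_scenario(mpg1 = 244, mpgx = 137, m = 1,
                         intercept_mode = "exact")
  expect_equal(mpg_from_hba1c(sc$hb1), 244, tolerance = 1e-9)
  expect_equal(mpg_from_hba1c(sc$hbx), 137, tolerance = 1e-9)
  sc2 <- mixture_scenario(hb1 = 9, hbx = 6, m = 1)
  expect_equal(sc2$mpg1, mpg_from_hba1c(9))
  expect_error(mixture_scenario(hb1 = 9, hbx = 6, m = 0), "\\(0, 4\\]")
  expect_error(mixture_scenario(hb1 = 9, hbx = 6, m = 4.5), "\\(0, 4\\]")
  expect_error(mixture_scenario(hb1 = -1, hbx = 6, m = 1), "positive")
  expect_error(mixture_scenario(hbx = 6, m = 1), "hb1")
})

test_that("cohort statistics reproduce the worked 9%-to-6% example", {
  sc <- mixture_scenario(hb1 = 9, hbx = 6, m = 1)
  expect_equal(phi_upper(sc), 13.5)
  expect_equal(phi_mean(sc), 6.75)
  expect_equal(delta_phi_mean(sc), 3)
  expect_equal(phi1(sc), 9.75)
  expect_equal(phi2(sc), 1.5)
  expect_equal(hb_mix(sc), 7.6875)
})

test_that("cohort statistics scale as stated for a half-month scenario", {
  sc <- mixture_scenario(hb1 = 12, hbx = 6.93, m = 0.5)
  expect_equal(phi_upper(sc), 12 * 3.5 / 2)        # 21.0
  expect_equal(phi_mean(sc), 10.5)
  expect_equal(delta_phi_mean(sc), 6.93 * 0.25)    # 1.7325
  expect_equal(phi1(sc), 12.2325)
  expect_equal(phi2(sc), 0.86625)
  # boundary behaviour
  expect_equal(phi_upper(mixture_scenario(hb1 = 9, hbx = 6, m = 4)), 0)
  expect_equal(phi2(mixture_scenario(hb1 = 9, hbx = 6, m = 4)), 6)
})

test_that("mixture equals the mass-weighted average of the two groups", {
  set.seed(42)
  for (i in 1:40) {
    sc <- mixture_scenario(hb1 = runif(1, 3, 16), hbx = runif(1, 3, 16),
                           m = runif(1, 0.01, 4))
    expect_equal(hb_mix(sc),
                 (phi2(sc) * sc$m + phi1(sc) * (4 - sc$m)) / 4,
                 tolerance = 1e-12)
    # bounded by the two steady states
    expect_gte(hb_mix(sc), min(sc$hb1, sc$hbx) - 1e-12)
    expect_lte(hb_mix(sc), max(sc$hb1, sc$hbx) + 1e-12)
  }
})

test_that("no change means no transient; full turnover reaches the new curve", {
  for (m in c(0.25, 1, 2.5, 4)) {
    expect_equal(hb_mix_value(7.5, 7.5, m), 7.5)
  }
  expect_equal(hb_mix_value(9, 6, 4), 6)
  expect_error(hb_mix_value(9, 6, 0), "\\(0, 4\\]")
})

test_that("mixture approaches the new curve monotonically", {
  m <- seq(0.05, 4, by = 0.05)
  falling <- hb_mix_value(9, 6, m)
  expect_true(all(diff(falling) < 0))
  rising <- hb_mix_value(6, 9, m)
  expect_true(all(diff(rising) > 0))
})

test_that("mixture is affine in each endpoint at fixed m", {
  m <- 1.3
  base <- hb_mix_value(8, 6, m)
  d_hb1 <- hb_mix_value(9, 6, m) - base
  expect_equal(hb_mix_value(10, 6, m) - hb_mix_value(9, 6, m), d_hb1)
  d_hbx <- hb_mix_value(8, 7, m) - base
  expect_equal(hb_mix_value(8, 8, m) - hb_mix_value(8, 7, m), d_hbx)
  # the two affine weights sum to one
  expect_equal(d_hb1 + d_hbx, 1)
})

test_that("MPG-space mixture agrees with the canonical HbA1c-space form", {
  # exact constants with exact conversions: identical by algebra
  sc <- mixture_scenario(hb1 = 9, hbx = 6, m = 1, intercept_mode = "exact")
  expect_equal(hb_mix(sc, space = "mpg", constant_mode = "exact"),
               hb_mix(sc), tolerance = 1e-12)
  # rounded 570/1236 constants with paper conversions: within 0.1 pp
  for (hb1 in c(5, 9, 14)) {
    for (m in c(0.5, 1, 2, 3.5)) {
      sc <- mixture_scenario(hb1 = hb1, hbx = 6, m = m)
      expect_equal(hb_mix(sc, space = "mpg", constant_mode = "paper"),
                   hb_mix(sc), tolerance = 0.1)
    }
  }
})
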