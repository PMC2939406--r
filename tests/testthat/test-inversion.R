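test_that("HbA1c-space inversion recovers the new curve exactly", {
  inv <- invert_hbx(hb_mix = 7.6875, hb1 = 9, m = 1)
  expect_equal(inv$hbx, 6)                          # (123 - 81) / 7
  expect_equal(inv$mpgx, mpg_from_hba1c(6))
  expect_length(inv$flags, 0)
  # steady state inverts to itself
  for (m in c(0.3, 1, 2, 4)) {
    expect_equal(invert_hbx(8, 8, m)$hbx, 8)
  }
  # half-month inversion is fixed by the closed form: 29 / 3.75
  expect_equal(invert_hbx(11, 12, 0.5)$hbx, 29 / 3.75)   # 7.7333...
  expect_error(invert_hbx(7, 9, 0), "denominator")
  expect_error(invert_hbx(7, 9, 5), "denominator")
})

test_that("inversion then mixture is the identity across the clinical range", {
  for (y in seq(3, 16, by = 1.3)) {
    for (hb1 in seq(3, 16, by = 1.3)) {
      for (m in c(0.5, 1, 2, 3, 4)) {
        hbx <- invert_hbx(y, hb1, m)$hbx
        expect_equal(hb_mix_value(hb1, hbx, m), y, tolerance = 1e-9)
      }
    }
  }
})

test_that("non-physiological inversions are flagged, never raised or clamped", {
  inv <- invert_hbx(hb_mix = 4, hb1 = 14, m = 0.5)
  expect_true(inv$hbx < 0)                # reported as computed
  expect_true("non_physiological" %in% inv$flags)
  expect_true(is.na(inv$mpgx))
})

test_that("MPG-space inversion matches its two constant conventions", {
  inv <- invert_mpgx(7.6875, 244, 1, constant_mode = "paper")
  expect_equal(inv$mpgx, (570 * 7.6875 - 244 * 9 - 1236) / 7)
  inv2 <- invert_mpgx(5, 208, 2, constant_mode = "paper")
  expect_equal(inv2$mpgx, (2850 - 832 - 1236) / 12)       # 65.17
  # fixed point: measuring the steady state returns the same glucose
  g <- mpg_from_hba1c(7)
  expect_equal(invert_mpgx(7, g, 2, constant_mode = "exact")$mpgx, g,
               tolerance = 1e-9)
  # the two conventions differ by exactly (0.4 hbmix + 0.8)/(8m - m^2)
  # mg/dl, which stays under 1.5 mg/dl once a full month has elapsed
  for (hbmix in seq(4, 14, by = 2.5)) {
    for (mpg1 in seq(100, 420, by = 80)) {
      for (m in c(0.5, 1, 2, 3, 4)) {
        p <- invert_mpgx(hbmix, mpg1, m, "paper")$mpgx
        e <- invert_mpgx(hbmix, mpg1, m, "exact")$mpgx
        if (!is.na(p) && !is.na(e)) {
          expect_equal(p - e, (0.4 * hbmix + 0.8) / (8 * m - m^2),
                       tolerance = 1e-9)
          if (m >= 1) expect_lt(abs(p - e), 1.5)
        }
      }
    }
  }
})

test_that("percent of total change is endpoint-free, fast early, complete at 4", {
  expect_equal(percent_change(1), 43.75)
  expect_equal(round_half_out(percent_change(1)), 44)
  expect_equal(percent_change(2), 75)
  expect_equal(percent_change(4), 100)
  expect_equal(percent_change(0), 0)
  # equals the endpoint-normalized mixture drop for any endpoints
  for (ends in list(c(9, 6), c(5, 13), c(12, 6.93))) {
    m <- c(0.5, 1, 2, 3, 4)
    drop <- 100 * (ends[1] - hb_mix_value(ends[1], ends[2], m)) /
      (ends[1] - ends[2])
    expect_equal(drop, percent_change(m), tolerance = 1e-12)
  }
  m <- seq(0, 4, by = 0.1)
  pc <- percent_change(m)
  expect_true(all(diff(pc) > 0))          # strictly increasing
  expect_true(all(diff(diff(pc)) < 0))    # decelerating ("prompt fall")
  expect_error(percent_change(4.2), "\\[0, 4\\]")
})

test_that("time course samples the mixture and its completion fraction", {
  tc <- time_course(hb1 = 12, hbx = 6.93)
  expect_s3_class(tc, "time_course")
  expect_equal(tc$hb_mix[tc$m == 4], 6.93)
  expect_equal(tc$hb_mix[tc$m == 2], 131.16 / 16)   # 8.1975
  expect_equal(tc$percent_complete[tc$m == 4], 100)
  expect_true(all(tc$hb_mix >= 6.93 & tc$hb_mix <= 12))
  expect_true(all(diff(tc$hb_mix) < 0))
  tc2 <- time_course(hb1 = 9, hbx = 6, grid = 1)
  expect_equal(tc2$hb_mix, 7.6875)
  expect_error(time_course(9, 6, grid = numeric(0)), "non-empty")
  expect_error(time_course(9, 6, grid = c(1, 5)), "\\(0, 4\\]")
})

test_that("crude-conversion error is zero at steady state, signed by direction", {
  g <- mpg_from_hba1c(6)
  expect_equal(estimation_error(6, g, 2, constant_mode = "exact"), 0,
               tolerance = 1e-12)
  # worked spot checks under paper constants
  expect_equal(estimation_error(5, 208, 2), 100 * (1 - 100.7 * 12 / 782))
  expect_equal(estimation_error(6, 101, 2), 100 * (1 - 136.3 * 12 / 1780))
  # improved control (hbx < hb1): crude conversion overestimates (negative)
  expect_lt(estimation_error(6, 244, 2), 0)
  # worsened control: underestimation (positive)
  expect_gt(estimation_error(10, 137, 2), 0)
  # unreachable glucose regimes carry the non-physiological marker
  err <- estimation_error(5, 420, 0.5)
  expect_true(is.na(err))
  expect_true(attr(err, "non_physiological"))
})

test_that("error grid masks out-of-range regimes like the published 2-month table", {
  eg <- error_grid(m = 2)
  expect_equal(dim(eg$cells), c(10, 10))
  expected_mask <- matrix(FALSE, 10, 10, dimnames = dimnames(eg$cells))
  expected_mask["5", c("244", "279", "315", "350", "385", "420")] <- TRUE
  expected_mask["6", c("315", "350", "385", "420")] <- TRUE
  expected_mask["7", c("385", "420")] <- TRUE
  expect_equal(eg$mask, expected_mask)
  # the 3-month grid has no out-of-range cells
  expect_false(any(error_grid(m = 3)$mask))
})

test_that("error grid signs and magnitudes follow the mismatch direction", {
  crude <- mpg_from_hba1c(5:14)
  for (m in c(2, 3)) {
    eg <- error_grid(m, mpg1_values = crude, hbmix_values = 5:14)
    # crude-consistent diagonal: near-zero under paper constants
    expect_true(all(abs(diag(eg$cells)) < 0.25))
    for (i in 1:10) {
      # tabulated (unmasked) cells left and right of the crude match
      above <- eg$cells[i, setdiff(seq_len(i - 1), which(eg$mask[i, ]))]
      below <- eg$cells[i, setdiff(seq(i, 10)[-1], which(eg$mask[i, ]))]
      expect_true(all(above > 0))                 # underestimation
      expect_true(all(below < 0))                 # overestimation
      # |error| grows with the baseline/measurement mismatch along a row
      expect_true(all(diff(abs(above)) < 0))
      expect_true(all(diff(abs(below)) > 0))
    }
  }
  # under exact constants the diagonal is exactly zero
  egx <- error_grid(2, mpg1_values = crude, hbmix_values = 5:14,
                    constant_mode = "exact")
  expect_equal(max(abs(diag(egx$cells))), 0, tolerance = 1e-12)
})

test_that("errors shrink as the measurement interval lengthens", {
  # under exact constants the shrinkage is strict cell-wise
  eg2x <- error_grid(2, constant_mode = "exact")
  eg3x <- error_grid(3, constant_mode = "exact")
  ok <- !eg2x$mask & !eg3x$mask
  expect_true(all(abs(eg3x$cells[ok]) <= abs(eg2x$cells[ok]) + 1e-12))
  # rounded paper constants leave a sub-0.25 offset on the
  # crude-consistent diagonal; off it the shrinkage still holds
  eg2 <- error_grid(2)
  eg3 <- error_grid(3)
  ok <- !eg2$mask & !eg3$mask & abs(eg2$cells) >= 0.25
  expect_true(all(abs(eg3$cells[ok]) <= abs(eg2$cells[ok]) + 1e-12))
})

test_that("error grid CSV writes masked cells blank and round-trips", {
  eg <- error_grid(m = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_error_grid_csv(eg, path)
  back <- read.csv(path, check.names = FALSE)
  expect_equal(back$hbmix, 5:14)
  expect_true(is.na(back[["420"]][1]))                   # masked corner
  expect_equal(back[["244"]][5], unname(eg$cells["9", "244"]))
})
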