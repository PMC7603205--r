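test_that("binomial coefficients are exact and handle edge cases", {
  expect_equal(binom_exact(9, 3), 84)
  expect_equal(binom_exact(192, 4), 54870480)
  expect_equal(binom_exact(c(0, 5, 17, 200), 0), c(1, 1, 1, 1))
  expect_equal(binom_exact(3, 7), 0)
  expect_error(binom_exact(-1, 2), "non-negative")
  expect_error(binom_exact(4, -2), "non-negative")
  expect_error(binom_exact(4.5, 2), "integers")
})

test_that("binomial symmetry and Pascal identity hold across the design range", {
  for (n in c(2, 5, 17, 48, 96, 123, 192, 200)) {
    for (r in 0:min(n, 6)) {
      expect_identical(binom_exact(n, r), binom_exact(n, n - r))
      if (n >= 1 && r >= 1)
        expect_identical(binom_exact(n, r),
                         binom_exact(n - 1, r - 1) + binom_exact(n - 1, r))
    }
  }
})

test_that("total combinations and unreduced positions match the worked examples", {
  expect_equal(total_combinations(dilution_cfg(3, 3)), 84)
  expect_equal(total_combinations(dilution_cfg(4, 48)), 54870480)
  expect_equal(total_combinations(dilution_cfg(2, 2)), 6)
  p <- positions_no_dilution(dilution_cfg(3, 3))
  expect_equal(as.numeric(p), 28)
  expect_true(attr(p, "integral"))
  p48 <- positions_no_dilution(dilution_cfg(4, 48))
  expect_equal(as.numeric(p48), 1143135)  # 54,870,480 / 48
  expect_equal(as.numeric(positions_no_dilution(instrument_config(1, 1, 1))), 1)
  # non-integral division is flagged, not hidden
  pf <- positions_no_dilution(instrument_config(1, 4, 2))
  expect_equal(as.numeric(pf), 1.5)
  expect_false(attr(pf, "integral"))
})

test_that("meaningful-combination closed form matches known values", {
  expect_equal(meaningful_combinations(3, 3), 27)
  expect_equal(meaningful_combinations(4, 48), 19906560)
  expect_equal(meaningful_combinations(2, 3), 12)
  for (r in 1:5) expect_equal(meaningful_combinations(r, r), r^r)
  expect_error(meaningful_combinations(4, 3), "n_rad")
  expect_error(meaningful_combinations(0, 3), "positive")
})

test_that("circumferential/radial decomposition is exact and consistent", {
  expect_equal(circumferential_combinations(4, 48), 778320)
  expect_equal(circumferential_combinations(3, 3), 3)
  expect_equal(circumferential_combinations(2, 10), 90)
  expect_equal(radial_combinations(4, 48), 19128240)
  expect_equal(radial_combinations(3, 3), 24)
  expect_equal(radial_combinations(2, 2), 2)
  # decomposition identity over a sweep
  for (r in 2:4) for (n in r:20)
    expect_equal(circumferential_combinations(r, n) + radial_combinations(r, n),
                 meaningful_combinations(r, n))
})

test_that("dilution-screen position counts divide exactly", {
  expect_equal(positions_with_dilution(4, 48), 414720)
  expect_equal(positions_with_dilution(3, 3), 9)
  expect_equal(positions_with_dilution(2, 2), 2)
  for (r in 1:5) for (n in r:12)
    expect_equal(positions_with_dilution(r, n) * n,
                 meaningful_combinations(r, n))
})

test_that("screen time model converts positions to days", {
  expect_equal(screen_time_days(414720, 10), 48)
  expect_equal(screen_time_days(0, 10), 0)
  expect_equal(screen_time_days(97200, 10), 11.25)
  expect_error(screen_time_days(-1), "non-negative")
})

test_that("single-ring ML time model reproduces tabulated durations", {
  expect_equal(round(ml_screen_time_days(4, 48), 4), 0.4692)
  expect_equal(round(ml_screen_time_days(3, 30), 4), 0.0073)
  expect_lt(ml_screen_time_days(2, 2), 1.5e-6)
})

test_that("the 27-row design table reconstructs every printed count exactly", {
  ref <- reference_design_table()
  dt <- design_table()
  expect_equal(nrow(dt), 27)
  expect_equal(dt$r, ref$r)
  expect_equal(dt$n_rad, ref$n_rad)
  expect_equal(dt$total_combinations, ref$n_combinations)
  expect_equal(dt$meaningful_combinations, ref$n_meaningful)
  expect_equal(dt$circumferential_combinations, ref$n_circ)
  expect_equal(dt$positions_with_dilution, ref$n_positions)
  ok <- !is.na(ref$n_radial)
  expect_equal(dt$radial_combinations[ok], ref$n_radial[ok])
  # the one malformed printed radial count: the formula value stands
  expect_equal(dt$radial_combinations[dt$r == 4 & dt$n_rad == 40], 9106440)
  # redundancy reduction always helps for r >= 2 (strict inequality)
  expect_true(all(dt$meaningful_combinations < dt$total_combinations))
})

test_that("design-table times match printed values to printed precision", {
  ref <- reference_design_table()
  dt <- design_table()
  exc <- time_exception_rows(ref)
  ok <- setdiff(seq_len(nrow(ref)), exc)
  expect_equal(length(ok), 25)
  expect_true(all(abs(dt$screen_time_days[ok] - as.numeric(ref$time[ok])) <=
                    half_ulp(ref$time[ok]) + 1e-12))
  # the flagged rows genuinely disagree with their own position counts; the
  # model value (positions x 10 s) stands
  expect_true(all(abs(dt$screen_time_days[exc] - as.numeric(ref$time[exc])) >
                    half_ulp(ref$time[exc])))
  expect_equal(dt$screen_time_days[dt$r == 3 & dt$n_rad == 48],
               6624 * 10 / 86400)
  # ML times agree within one unit in the last printed digit on every row
  expect_true(all(abs(dt$ml_screen_time_days - as.numeric(ref$time_ml)) <=
                    2 * half_ulp(ref$time_ml) + 1e-12))
})

test_that("design_counts exposes the unreduced decomposition identity", {
  for (r in 2:4) for (n in c(r, r + 2, 10)) {
    dc <- design_counts(r, n)
    expect_equal(dc$circumferential_no_dilution + dc$radial_no_dilution,
                 dc$total_combinations)
  }
})
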