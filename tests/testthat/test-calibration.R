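test_that("level/amplification/SPL conversions match the published table", {
  tab <- default_calibration()

  expect_equal(hl_to_amplification(tab, 1000, 70), 85)
  expect_equal(hl_to_amplification(tab, 1000, 0), 15)
  expect_equal(hl_to_amplification(tab, 500, 70), 90)

  expect_equal(hl_to_spl(tab, 6000, 70), 92.8)
  expect_equal(hl_to_spl(tab, 4000, 0), -3.9)
  expect_equal(hl_to_spl(tab, 250, 70), 89.6)

  # SPL at the calibration point reproduces every parenthesised value:
  # 70 dB HL for the directly calibrated rows, the level reachable at
  # maximum amplification for the extrapolated rows
  ref <- printed_calibration
  level <- ifelse(ref$measured_at_max, 100 - ref$ref_amplification_db, 70)
  expect_equal(hl_to_spl(tab, ref$frequency_hz, level), ref$measured_spl)
})

test_that("conversions reject unknown frequencies and off-grid levels", {
  tab <- default_calibration()
  expect_error(hl_to_amplification(tab, 999, 40), "not in calibration")
  expect_error(hl_to_spl(tab, 11000, 40), "not in calibration")
  expect_error(measurable_range(tab, 300), "not in calibration")
  expect_error(hl_to_amplification(tab, 1000, 90), "above maximum")
  expect_error(hl_to_amplification(tab, 1000, -15), "below minimum")
  expect_error(hl_to_amplification(tab, 1000, 12), "grid")
})

test_that("round trip hl -> amplification -> hl is exact on the whole grid", {
  tab <- default_calibration()
  for (f in tab$frequency_hz) {
    rng <- measurable_range(tab, f)
    levels <- seq(rng$min_hl, rng$max_hl - 5, by = 5)
    amp <- hl_to_amplification(tab, rep(f, length(levels)), levels)
    expect_identical(amplification_to_hl(tab, rep(f, length(levels)), amp),
                     levels)
  }
})

test_that("digital amplitude map: endpoints, silence and log-linearity", {
  expect_identical(amplification_to_amplitude(100), 1)
  expect_identical(amplification_to_amplitude(0), 0)
  expect_equal(amplification_to_amplitude(80), 0.1)
  expect_error(amplification_to_amplitude(-5), ">= 0")
  expect_error(amplification_to_amplitude(105), "above maximum")

  amps <- seq(5, 100, by = 5)
  lin <- amplification_to_amplitude(amps)
  expect_true(all(diff(lin) > 0))
  a20 <- seq(5, 80, by = 5)
  expect_equal(amplification_to_amplitude(a20 + 20),
               10 * amplification_to_amplitude(a20))
})

test_that("measurable ranges derive from the amplification bounds", {
  tab <- default_calibration()
  rng <- measurable_range(tab)
  expect_equal(rng$min_hl, 5 - tab$ref_amplification_db)
  expect_equal(rng$max_hl, 100 - tab$ref_amplification_db + 5)
  expect_true(all(rng$min_hl %% 5 == 0) && all(rng$max_hl %% 5 == 0))
  expect_true(all(rng$min_hl < rng$max_hl))

  r1k <- measurable_range(tab, 1000)
  expect_equal(c(r1k$min_hl, r1k$max_hl), c(-10, 90))
  r16k <- measurable_range(tab, 16000)
  expect_equal(c(r16k$min_hl, r16k$max_hl), c(-45, 55))
  r125 <- measurable_range(tab, 125)
  expect_equal(c(r125$min_hl, r125$max_hl), c(-30, 70))
})

test_that("RETSPL extrapolation from the saturation ceiling", {
  expect_equal(estimate_retspl_from_ceiling(102.8, 50), 52.8)
  expect_equal(estimate_retspl_from_ceiling(102.2, 35), 37.2)
  expect_equal(estimate_retspl_from_ceiling(98.3, 35), 33.3)
  expect_equal(estimate_retspl_from_ceiling(100.0, 100), 100.0)
  expect_error(estimate_retspl_from_ceiling(100, 105), "exceeds")

  # consistency with hl_to_spl: at the HL reachable at maximum
  # amplification, the predicted SPL equals the measured ceiling SPL
  tab <- default_calibration()
  star <- printed_calibration[printed_calibration$measured_at_max, ]
  hl_at_max <- 100 - star$ref_amplification_db
  expect_equal(hl_to_spl(tab, star$frequency_hz, hl_at_max),
               star$measured_spl, tolerance = 1e-9)
})

test_that("calibration adjustment rounds deviations to multiples of 5", {
  tab <- default_calibration()

  # the pre-calibration mean deviation (-0.63 dB) rounds to 0: unchanged
  adj <- adjust_calibration(tab, -0.63)
  expect_equal(adj$ref_amplification_db, tab$ref_amplification_db)

  diffs <- tibble::tibble(frequency_hz = tab$frequency_hz,
                          mean_diff_db = 0)
  diffs$mean_diff_db[diffs$frequency_hz == 2000] <- 6
  adj <- adjust_calibration(tab, diffs)
  expect_equal(adj$ref_amplification_db[adj$frequency_hz == 2000],
               tab$ref_amplification_db[tab$frequency_hz == 2000] + 5)
  expect_equal(adj$ref_amplification_db[adj$frequency_hz != 2000],
               tab$ref_amplification_db[tab$frequency_hz != 2000])
  # original untouched
  expect_equal(tab$ref_amplification_db[tab$frequency_hz == 2000], 15)

  # brute-force nearest-multiple oracle over a grid of deviations
  cand <- seq(-30, 30, by = 5)
  for (d in c(-7.4, -2.5, 2.5, 7.5, 12.4, -12.6)) {
    nearest <- cand[order(abs(cand - d),
                          -abs(cand))][1]  # half away from zero
    expect_equal(puretone:::round_to_multiple(d), nearest,
                 info = paste("deviation", d))
  }

  expect_error(adjust_calibration(tab, tibble::tibble(
    frequency_hz = c(1000, 2000), mean_diff_db = c(5, 5))),
    "one difference per table frequency")
})

test_that("calibration tables round-trip through CSV and validate", {
  tab <- default_calibration()
  path <- withr::local_tempfile(fileext = ".csv")
  write_calibration(tab, path)
  back <- read_calibration(path)
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(tab))

  # the packaged CSV is identical to the in-code default
  pkg_csv <- system.file("extdata", "retspl_dt770.csv",
                         package = "puretone")
  expect_equal(tibble::as_tibble(read_calibration(pkg_csv)),
               tibble::as_tibble(tab))

  expect_error(calibration_table(tab[, 1:2]), "lack column")
  expect_error(calibration_table(rbind(tab, tab[1, ])), "duplicate")
  bad <- tibble::as_tibble(tab)
  bad$ref_amplification_db[1] <- 120
  expect_error(calibration_table(bad), "out of")
})
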