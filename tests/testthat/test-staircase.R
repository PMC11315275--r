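test_that("hand-traced track: descending start validates on the second inversion", {
  tab <- default_calibration()
  cfg <- procedure_config("aupiometer")
  res <- run_track(det_listener_at(1000, 20), 1000, cfg, tab)
  expect_equal(res$threshold_hl, 20)
  expect_equal(res$status, "validated")
  trials <- attr(res, "trials")
  expect_equal(trials$level_hl, c(40, 30, 20, 10, 15, 20))
  expect_equal(trials$response, c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE))
})

test_that("ascending start: three inversions for aupiometer, one for elios", {
  tab <- default_calibration()
  res_a <- run_track(det_listener_at(1000, 50), 1000,
                     procedure_config("aupiometer"), tab)
  expect_equal(attr(res_a, "trials")$level_hl, c(40, 45, 50, 40, 45, 50))
  expect_equal(res_a$threshold_hl, 50)

  res_e <- run_track(det_listener_at(1000, 50), 1000,
                     procedure_config("elios"), tab)
  expect_equal(attr(res_e, "trials")$level_hl, c(40, 45, 50))
  expect_equal(res_e$threshold_hl, 50)
})

test_that("single-step transitions follow the -10/+5 rule with clipping", {
  tab <- default_calibration()
  cfg <- procedure_config("aupiometer")
  rng <- measurable_range(tab, 1000)
  st <- new_staircase(cfg, rng)
  expect_equal(next_level(st, cfg), 40)
  st_hit <- update_staircase(st, 40, TRUE, cfg)
  expect_equal(next_level(st_hit, cfg), 30)
  st_miss <- update_staircase(st, 40, FALSE, cfg)
  expect_equal(next_level(st_miss, cfg), 45)

  # clipping at the presentable maximum (85 at 1 kHz; 90 is the recorded
  # ceiling value, not a presentable level)
  st2 <- st
  st2$current_level_hl <- 85
  st2 <- update_staircase(st2, 85, FALSE, cfg)
  expect_equal(st2$status, "ceiling")
  expect_equal(st2$threshold_hl, 90)

  # updating a terminated staircase is a state error
  expect_error(update_staircase(st2, 85, FALSE, cfg), "terminated")
  expect_error(next_level(st2, cfg), "terminated")
})

test_that("never-responding listener records range max with ceiling status", {
  tab <- default_calibration()
  cfg <- procedure_config("aupiometer")
  res <- run_track(det_listener_at(1000, 999), 1000, cfg, tab)
  expect_equal(res$threshold_hl, 90)
  expect_equal(res$status, "ceiling")
  res16 <- run_track(det_listener_at(16000, 999), 16000, cfg, tab)
  expect_equal(res16$threshold_hl, 55)
})

test_that("always-responding listener records range min with floor status", {
  tab <- default_calibration()
  cfg <- procedure_config("aupiometer")
  res <- run_track(det_listener_at(1000, -100), 1000, cfg, tab)
  expect_equal(res$threshold_hl, -10)
  expect_equal(res$status, "floor")
})

test_that("oracle equivalence over every frequency, grid threshold and variant", {
  tab <- default_calibration()
  for (variant in c("aupiometer", "elios")) {
    cfg <- procedure_config(variant)
    for (f in tab$frequency_hz) {
      rng <- measurable_range(tab, f)
      for (t_hl in seq(rng$min_hl, rng$max_hl - 5, by = 5)) {
        res <- run_track(det_listener_at(f, t_hl), f, cfg, tab,
                         keep_trials = FALSE)
        expect_equal(res$threshold_hl, t_hl,
                     info = paste(variant, f, "Hz, T =", t_hl))
      }
    }
  }
})

test_that("off-grid deterministic thresholds land on the next 5-dB step up", {
  tab <- default_calibration()
  cfg <- procedure_config("aupiometer")
  rng <- measurable_range(tab, 2000)
  set.seed(11)
  for (t_hl in c(-9.9, -2.5, 0.1, 23, 37.5, 61.2, 84.9)) {
    res <- run_track(det_listener_at(2000, t_hl), 2000, cfg, tab,
                     keep_trials = FALSE)
    expect_equal(res$threshold_hl,
                 oracle_threshold(t_hl, rng$min_hl, rng$max_hl),
                 info = paste("T =", t_hl))
  }
})

test_that("raising a deterministic threshold never lowers the estimate", {
  tab <- default_calibration()
  cfg <- procedure_config("elios")
  set.seed(3)
  ts <- sort(runif(25, -20, 95))
  est <- vapply(ts, function(t_hl) {
    run_track(det_listener_at(4000, t_hl), 4000, cfg, tab,
              keep_trials = FALSE)$threshold_hl
  }, numeric(1))
  expect_true(all(diff(est) >= 0))
})

test_that("variants differ only when the first trial is a miss", {
  tab <- default_calibration()
  cfg_a <- procedure_config("aupiometer")
  cfg_e <- procedure_config("elios")
  for (t_hl in seq(-10, 85, by = 5)) {
    tr_a <- attr(run_track(det_listener_at(1000, t_hl), 1000, cfg_a, tab),
                 "trials")
    tr_e <- attr(run_track(det_listener_at(1000, t_hl), 1000, cfg_e, tab),
                 "trials")
    if (t_hl <= 40) {
      expect_identical(tr_a$level_hl, tr_e$level_hl,
                       info = paste("T =", t_hl))
    }
    # thresholds agree regardless
    expect_equal(tr_a$level_hl[nrow(tr_a)], tr_e$level_hl[nrow(tr_e)])
  }
})

test_that("every presented level stays presentable; validated tracks end on a detection", {
  tab <- default_calibration()
  cfg <- procedure_config("aupiometer")
  set.seed(5)
  for (i in 1:30) {
    f <- sample(tab$frequency_hz, 1)
    rng <- measurable_range(tab, f)
    listener <- listener_model(stats::setNames(runif(1, -30, 80), f),
                               slope_db = 4)
    res <- run_track(listener, f, cfg, tab)
    trials <- attr(res, "trials")
    expect_true(all(trials$level_hl >= rng$min_hl &
                      trials$level_hl <= rng$max_hl - 5))
    if (res$status == "validated") {
      expect_true(trials$response[nrow(trials)])
      expect_equal(res$threshold_hl, trials$level_hl[nrow(trials)])
      expect_equal(res$threshold_hl %% 5, 0)
    }
  }
})

test_that("inter-trial pauses are drawn within the configured bounds", {
  tab <- default_calibration()
  cfg <- procedure_config("aupiometer")
  set.seed(8)
  res <- run_track(listener_model(c("1000" = 30)), 1000, cfg, tab)
  iti <- attr(res, "trials")$iti_ms
  expect_true(all(iti >= 2000 & iti <= 4000))
})

test_that("sessions test all 15 frequencies in the prescribed order and reproduce under a seed", {
  tab <- default_calibration()
  cfg <- procedure_config("aupiometer")
  expect_equal(cfg$frequency_order_hz,
               c(1000, 1500, 2000, 3000, 4000, 6000, 8000, 10000, 12500,
                 14000, 16000, 750, 500, 250, 125))

  flat <- deterministic_listener(flat_thresholds(5, tab))
  ag <- run_session(flat, cfg, tab, seed = 2)
  expect_equal(ag$frequency_hz, as.integer(cfg$frequency_order_hz))
  expect_true(all(ag$threshold_hl == 5))

  noisy <- listener_model(flat_thresholds(10, tab), slope_db = 4)
  ag1 <- run_session(noisy, cfg, tab, seed = 123)
  ag2 <- run_session(noisy, cfg, tab, seed = 123)
  expect_identical(ag1, ag2)
})

test_that("the trial cap aborts a track that cannot terminate in time", {
  tab <- default_calibration()
  cfg <- procedure_config("aupiometer", max_trials = 3)
  res <- run_track(det_listener_at(1000, 20), 1000, cfg, tab)
  expect_equal(res$status, "aborted")
  expect_true(is.na(res$threshold_hl))
  expect_equal(res$n_trials, 3)
})
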