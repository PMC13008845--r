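# Synthetic EEG screens: determinism, calibration, injection locality,
# statistics and adaptive labeling.

test_that("generation is deterministic for a fixed seed", {
  cfg <- tiny_config(seed = 123)
  a <- generate_background(cfg)
  b <- generate_background(cfg)
  expect_identical(a$data, b$data)
  expect_identical(a$trial_stats, b$trial_stats)
})

test_that("zero-noise limit reduces to the ERP template on every channel", {
  cfg <- tiny_config(noise_gain = 0, quality_level = 1, seed = 1)
  scr <- generate_background(cfg)
  tpl <- yolobt:::erp_template(cfg)
  for (tr in c(1, 5, 10))
    for (ch in c(1, 8))
      expect_equal(scr$data[ch, tr, ], tpl, tolerance = 1e-12)
  expect_false(any(scr$trial_labels))
})

test_that("default background stays in the clean band (Monte Carlo)", {
  # calibration of noise_gain against the 500 uV band edge: the median
  # clean-trial Max PTP over many seeded screens must stay below it
  meds <- vapply(1:40, function(s) {
    scr <- generate_background(gen_config(seed = s))
    stats::median(scr$trial_stats$max_ptp)
  }, 0)
  expect_lt(stats::median(meds), 500)
  expect_lt(max(meds), 500)  # comfortably inside, not borderline
})

test_that("configuration errors are caught", {
  expect_error(gen_config(sfreq = 0), "sfreq")
  expect_error(gen_config(trial_len = -1), "trial_len")
  expect_error(gen_config(quality_level = 1.2), "quality_level")
  expect_error(artifact_spec("blink", 1, 0, 0.1, 10), "kind")
  expect_error(artifact_spec("emg", 1, 0, -0.1, 10), "duration")
  expect_error(artifact_spec("emg", 1, 0, 0.1, -5), "amplitude")
})

test_that("injection is additive, local and exactly recorded", {
  cfg <- tiny_config(seed = 7)
  scr <- generate_background(cfg)
  spec <- artifact_spec("emg", channels = 2:3, onset = 0.1,
                        duration = 0.2, amplitude = 800)
  out <- inject_artifact(scr, trial = 4, spec)
  # amplitude 0 is the identity on the data
  zspec <- artifact_spec("emg", 2:3, 0.1, 0.2, 0)
  expect_identical(inject_artifact(scr, 4, zspec)$data, scr$data)
  # unlisted channels / other trials / samples outside the window are
  # bitwise unchanged
  expect_identical(out$data[-(2:3), , ], scr$data[-(2:3), , ])
  expect_identical(out$data[, -4, ], scr$data[, -4, ])
  i0 <- 1 + floor(0.1 * cfg$sfreq + 1e-9)
  i1 <- ceiling(0.3 * cfg$sfreq - 1e-9)
  expect_identical(out$data[2:3, 4, -(i0:i1)], scr$data[2:3, 4, -(i0:i1)])
  expect_false(identical(out$data[2, 4, i0:i1], scr$data[2, 4, i0:i1]))
  expect_length(out$injected, 1L)
  expect_equal(out$injected[[1]]$trial, 4L)
  # errors
  expect_error(inject_artifact(scr, 11, spec), "trial index")
  expect_error(inject_artifact(scr, 1, artifact_spec("emg", 99, 0, 0.1, 1)),
               "channels out of range")
})

test_that("high-amplitude emg drives Max PTP past the severe edge", {
  cfg <- tiny_config(seed = 8)
  scr <- generate_background(cfg)
  spec <- artifact_spec("emg", 1:4, 0.05, 0.3, amplitude = 4000)
  out <- inject_artifact(scr, 2, spec)
  # brute-force oracle: max over channels of (max - min) per sample vector
  ptp <- max(apply(out$data[, 2, ], 1, function(x) max(x) - min(x)))
  expect_equal(out$trial_stats$max_ptp[2], ptp, tolerance = 1e-12)
  expect_gt(out$trial_stats$max_ptp[2], 3000)
})

test_that("trial statistics follow the exclusion rule", {
  cfg <- tiny_config(noise_gain = 0, seed = 1, erp_amplitude = 0)
  scr <- generate_background(cfg)
  # constant (zero) signal
  expect_equal(scr$trial_stats$max_ptp, rep(0, 10))
  expect_equal(scr$trial_stats$max_std, rep(0, 10))
  # single +A spike on a zero baseline
  scr$data[3, 5, 10] <- 42
  st <- compute_trial_stats(scr)
  expect_equal(st$max_ptp[5], 42)
  # the same spike on a channel marked bad does not count
  scr$bad_channel_mask[3] <- TRUE
  st2 <- compute_trial_stats(scr)
  expect_equal(st2$max_ptp[5], 0)
  scr$bad_channel_mask[] <- TRUE
  expect_error(compute_trial_stats(scr), "all channels")
})

test_that("calibrated severities land in their bands for every kind", {
  cfg <- gen_config(seed = 99)
  scr <- generate_background(cfg)
  kinds <- c("signal_noise", "eye_movement", "emg", "movement")
  for (kind in kinds) {
    sev <- inject_artifact(scr, 1, calibrate_severity(kind, "severe", cfg))
    expect_gt(sev$trial_stats$max_ptp[1], 3000)
    mod <- inject_artifact(scr, 2, calibrate_severity(kind, "moderate", cfg))
    p <- mod$trial_stats$max_ptp[2]
    expect_true(p > 500 && p <= 3000)
    cl <- calibrate_severity(kind, "clean", cfg)
    expect_equal(cl$amplitude, 0)
    # monotonicity: severe amplitude strictly above moderate
    expect_gt(calibrate_severity(kind, "severe", cfg)$amplitude,
              calibrate_severity(kind, "moderate", cfg)$amplitude)
  }
  expect_error(calibrate_severity("emg", "extreme", cfg), "band")
})

test_that("screen datasets respect the mix and the ten-trial layout", {
  cfg <- gen_config(seed = 1)
  screens <- make_screen_dataset(cfg, 12, mix = c(clean = 0.5,
                                                  moderate = 0.2,
                                                  severe = 0.3), seed = 4)
  expect_length(screens, 12L)
  for (scr in screens) {
    expect_equal(dim(scr$data)[2], 10L)
    expect_length(scr$trial_labels, 10L)
    # band correctness for the recorded injections
    for (inj in scr$injected) {
      p <- scr$trial_stats$max_ptp[inj$trial]
      if (inj$spec$amplitude >= 3600) expect_gt(p, 3000)
    }
  }
  # all-clean mix: no bad labels anywhere
  clean <- make_screen_dataset(cfg, 5, mix = c(clean = 1), seed = 5)
  expect_false(any(unlist(lapply(clean, `[[`, "trial_labels"))))
  expect_error(make_screen_dataset(cfg, 0, seed = 1), "n_screens")
  expect_error(make_screen_dataset(cfg, 2, mix = c(clean = 0.4), seed = 1),
               "sum to 1")
})

test_that("realized bad fraction tracks the requested mix (Monte Carlo)", {
  cfg <- gen_config(seed = 1)
  # on clean-quality screens every injected moderate/severe trial is bad
  screens <- make_screen_dataset(cfg, 40, mix = c(clean = 0.7,
                                                  moderate = 0.1,
                                                  severe = 0.2),
                                 quality_range = c(1, 1),
                                 bad_channel_prob = 0, seed = 6)
  frac <- mean(unlist(lapply(screens, `[[`, "trial_labels")))
  expect_lt(abs(frac - 0.3), 0.05)
})

test_that("identical artifacts are bad on clean screens, tolerated on noisy", {
  cfg_clean <- gen_config(quality_level = 1, seed = 31)
  cfg_noisy <- gen_config(quality_level = 0, seed = 32)
  spec <- artifact_spec("emg", 40:50, 0.2, 0.4, amplitude = 1000)
  lab <- function(cfg) {
    scr <- generate_background(cfg)
    scr <- inject_artifact(scr, 5, spec)
    med <- stats::median(scr$trial_stats$max_ptp[-5])
    thr <- max(500, 3 * med)
    scr$trial_stats$max_ptp[5] > thr
  }
  expect_true(lab(cfg_clean))
  expect_false(lab(cfg_noisy))
})

test_that("screens round-trip through the serialization format", {
  cfg <- tiny_config(seed = 17)
  screens <- make_screen_dataset(cfg, 3, mix = c(clean = 0.6, severe = 0.4),
                                 seed = 17)
  dir <- withr::local_tempdir()
  save_screens(screens, dir)
  back <- load_screens(dir)
  expect_length(back, 3L)
  for (i in 1:3) {
    expect_equal(back[[i]]$data, screens[[i]]$data, tolerance = 1e-12)
    expect_identical(back[[i]]$trial_labels, screens[[i]]$trial_labels)
    expect_identical(back[[i]]$bad_channel_mask,
                     screens[[i]]$bad_channel_mask)
    expect_equal(back[[i]]$trial_stats, screens[[i]]$trial_stats,
                 tolerance = 1e-12)
    expect_length(back[[i]]$injected, length(screens[[i]]$injected))
  }
})
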