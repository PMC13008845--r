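# Rendering conventions, box geometry and label IO.

test_that("a ten-trial screen renders exactly nine dashed separators", {
  cfg <- tiny_config(noise_gain = 0, erp_amplitude = 0, seed = 1)
  scr <- generate_background(cfg)
  rc <- render_config(width = 200, height = 120)
  img <- render_screen(scr, rc)
  sep_cols <- which(vapply(seq_len(200), function(x)
    any(abs(img[, x, 3] - rc$separator_color[3]) < 1e-9 &
        abs(img[, x, 1] - rc$separator_color[1]) < 1e-9), TRUE))
  expect_length(sep_cols, 9L)
  expect_equal(sep_cols, round(200 * (1:9) / 10))
  # dashes: within a separator column, blue pixels alternate 6 on / 6 off
  # (waveforms are drawn after separators, so exclude rows they overdraw)
  on <- abs(img[, sep_cols[1], 3] - rc$separator_color[3]) < 1e-9
  wf <- img[, sep_cols[1], 1] == rc$waveform_color[1] &
    img[, sep_cols[1], 2] == rc$waveform_color[2]
  pattern <- (seq_len(120) - 1) %% 12 < 6
  expect_equal(which(on), setdiff(which(pattern), which(wf)))
  expect_false(any(on & !pattern))
})

test_that("bad channels draw in the bad-channel color", {
  cfg <- tiny_config(seed = 2)
  scr <- generate_background(cfg)
  scr$bad_channel_mask[] <- TRUE
  rc <- render_config(width = 160, height = 80)
  img <- render_screen(scr, rc)
  cols <- unique(round(c(img[, , 1], img[, , 2], img[, , 3]), 6))
  # only background, separator and bad-channel components appear
  allowed <- round(unique(c(rc$background_color, rc$separator_color,
                            rc$bad_channel_color)), 6)
  expect_true(all(cols %in% allowed))
  wf <- round(rc$waveform_color, 6)
  expect_false(any(img[, , 1] == wf[1] & img[, , 2] == wf[2] &
                     img[, , 3] == wf[3]))
})

test_that("rendering is a pure function of screen and config", {
  cfg <- tiny_config(seed = 3)
  scr <- generate_background(cfg)
  rc <- render_config(width = 96, height = 96)
  expect_identical(render_screen(scr, rc), render_screen(scr, rc))
})

test_that("waveforms never escape their channel rows", {
  cfg <- tiny_config(n_channels = 4L, seed = 4)
  scr <- generate_background(cfg)
  # an extreme artifact must saturate, not overrun neighbouring rows
  scr <- inject_artifact(scr, 3, artifact_spec("emg", 2, 0.05, 0.4, 50000))
  rc <- render_config(width = 120, height = 120)
  img <- render_screen(scr, rc)
  wf <- rc$waveform_color
  is_wf <- img[, , 1] == wf[1] & img[, , 2] == wf[2] & img[, , 3] == wf[3]
  rows_per_ch <- 120 / 4
  for (ch in 1:4) {
    rows <- which(apply(is_wf, 1, any))
    in_row <- rows[rows > (ch - 1) * rows_per_ch & rows <= ch * rows_per_ch]
  }
  # channel 2's waveform pixels all stay inside rows (30, 60]
  ch2 <- which(apply(is_wf[31:60, , drop = FALSE], 1, any))
  expect_true(length(ch2) > 0)
  other <- is_wf
  other[31:60, ] <- FALSE
  # remaining waveform pixels belong to channels 1, 3, 4 rows only
  expect_true(all(which(apply(other, 1, any)) %in% c(1:30, 61:120)))
})

test_that("bad-trial boxes follow the layout arithmetic", {
  cfg <- tiny_config(seed = 5)
  scr <- generate_background(cfg)
  scr$trial_labels[c(1, 2, 9)] <- TRUE
  b <- boxes_for_bad_trials(scr)
  expect_equal(nrow(b), 3L)
  expect_equal(b[, "cx"], c(0.05, 0.15, 0.85))
  expect_equal(b[, "cy"], rep(0.5, 3))
  expect_equal(b[, "w"], rep(0.1, 3))
  expect_equal(b[, "h"], rep(1, 3))
  expect_equal(b[, "class"], rep(0, 3))
  scr$trial_labels[] <- FALSE
  expect_equal(nrow(boxes_for_bad_trials(scr)), 0L)
  scr$trial_labels[1] <- TRUE
  expect_equal(unname(boxes_for_bad_trials(scr)[1, ]),
               c(0, 0.05, 0.5, 0.1, 1))
})

test_that("box extents tile [0,1] in tenths and match bad-trial counts", {
  cfg <- tiny_config(seed = 6)
  scr <- generate_background(cfg)
  scr$trial_labels[] <- TRUE
  b <- boxes_for_bad_trials(scr)
  expect_equal(nrow(b), 10L)
  lefts <- sort(b[, "cx"] - b[, "w"] / 2)
  rights <- sort(b[, "cx"] + b[, "w"] / 2)
  expect_equal(lefts, seq(0, 0.9, by = 0.1), tolerance = 1e-12)
  expect_equal(rights, seq(0.1, 1, by = 0.1), tolerance = 1e-12)
})

test_that("label files round-trip exactly at 6 decimals", {
  b <- rbind(box_row(0.05), box_row(0.85, w = 0.1))
  f <- withr::local_tempfile(fileext = ".txt")
  write_labels(b, f)
  expect_equal(read_labels(f), b, tolerance = 1e-12,
               ignore_attr = "dimnames")
  expect_identical(readLines(f)[1], "0 0.050000 0.500000 0.100000 1.000000")
  # empty list -> empty file -> empty list
  write_labels(b[0, , drop = FALSE], f)
  expect_identical(readLines(f), character(0))
  expect_equal(nrow(read_labels(f)), 0L)
  # malformed line names its number
  writeLines(c("0 0.1 0.5 0.1 1.0", "0 oops 0.5"), f)
  expect_error(read_labels(f), "line 2")
})

test_that("ppm files round-trip to 8-bit precision", {
  set.seed(7)
  img <- array(runif(24 * 16 * 3), c(24, 16, 3))
  f <- withr::local_tempfile(fileext = ".ppm")
  write_ppm(img, f)
  back <- read_ppm(f)
  expect_equal(dim(back), dim(img))
  expect_lt(max(abs(back - img)), 0.5 / 255 + 1e-9)
})

test_that("render_dataset writes images, labels and a manifest", {
  cfg <- tiny_config(seed = 8)
  screens <- make_screen_dataset(cfg, 6, mix = c(clean = 0.5, severe = 0.5),
                                 seed = 8)
  dir <- withr::local_tempdir()
  info <- render_dataset(screens, dir, render_config(width = 64, height = 64),
                         seed = 1)
  expect_length(list.files(dir, pattern = "\\.ppm$"), 6L)
  expect_length(list.files(dir, pattern = "\\.txt$"), 6L)
  man <- yaml_read(file.path(dir, "manifest.yaml"))
  expect_equal(man$n, 6)
  expect_equal(sort(table(info$split), decreasing = TRUE)[[1]],
               sum(info$split == "train"))
  # labels agree with the screens
  for (i in seq_along(screens)) {
    lab <- read_labels(file.path(dir, sprintf("screen_%04d.txt", i)))
    expect_equal(nrow(lab), sum(screens[[i]]$trial_labels))
  }
})
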