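# Evaluation metrics against worked examples and brute-force oracles.

det <- function(cx, conf, w = 0.1, cy = 0.5, h = 1) {
  if (!length(cx))
    return(data.frame(cx = numeric(), cy = numeric(), w = numeric(),
                      h = numeric(), conf = numeric()))
  data.frame(cx = cx, cy = cy, w = w, h = h, conf = conf)
}

test_that("match_detections implements greedy single matching", {
  truth <- box_row(0.25)
  m <- match_detections(det(0.25, 0.9), truth)
  expect_equal(m[c("TP", "FP", "FN")], list(TP = 1L, FP = 0L, FN = 0L))
  m <- match_detections(det(numeric(0), numeric(0)),
                        rbind(box_row(0.25), box_row(0.45)))
  expect_equal(m$FN, 2L)
  # two detections on one truth: only the higher-confidence one matches
  m <- match_detections(det(c(0.25, 0.26), c(0.8, 0.9)), truth)
  expect_equal(m$TP, 1L)
  expect_equal(m$FP, 1L)
  expect_true(m$det_tp[2])  # the 0.9 one
  expect_error(match_detections(det(0.5, 1.5), truth), "confidences")
})

test_that("precision_recall handles the zero conventions", {
  expect_equal(unname(precision_recall(list(TP = 1, FP = 0, FN = 0))),
               c(1, 1))
  expect_warning(
    pr <- precision_recall(list(TP = 0, FP = 0, FN = 2)), "precision")
  expect_equal(unname(pr), c(0, 0))
  expect_equal(unname(precision_recall(list(TP = 3, FP = 1, FN = 2))),
               c(0.75, 0.6))
  expect_error(precision_recall(list(TP = -1, FP = 0, FN = 0)),
               "non-negative")
})

test_that("f1_score reproduces the printed detector-table cells", {
  # percent-scale worked examples, rounded to 2 decimals
  expect_equal(round(f1_score(88.76, 86.89), 2), 87.82)
  expect_equal(round(f1_score(86.36, 82.01), 2), 84.13)
  # harmonic-mean fixed point and bounds
  expect_equal(f1_score(0.37, 0.37), 0.37)
  set.seed(40)
  for (i in 1:50) {
    p <- runif(1); r <- runif(1)
    f <- f1_score(p, r)
    expect_gte(f, min(p, r) - 1e-12)
    expect_lte(f, max(p, r) + 1e-12)
  }
  expect_equal(f1_score(0, 0), 0)
})

test_that("average_precision matches the exhaustive threshold sweep", {
  # perfect ranking: all truths found before any FP
  r <- average_precision(c(TRUE, TRUE, FALSE), c(0.9, 0.8, 0.3), 2)
  expect_equal(r$ap, 1)
  # one TP covering 1 of 2 truths, no FPs
  expect_equal(average_precision(TRUE, 0.8, 2)$ap, 0.5)
  # random instances vs the brute-force oracle
  set.seed(41)
  for (i in 1:25) {
    nd <- sample(1:20, 1)
    tp <- runif(nd) < 0.5
    conf <- round(runif(nd), 2)  # ties exercised
    nt <- sum(tp) + sample(0:3, 1)
    if (nt == 0) next
    expect_equal(average_precision(tp, conf, nt)$ap,
                 ap_oracle(tp, conf, nt), tolerance = 1e-12)
  }
})

test_that("interpolated AP variants bound the plain sum sensibly", {
  set.seed(42)
  tp <- runif(12) < 0.6
  conf <- runif(12)
  plain <- average_precision(tp, conf, 8)$ap
  ap11 <- average_precision(tp, conf, 8, "11point")$ap
  ap101 <- average_precision(tp, conf, 8, "101point")$ap
  expect_true(all(c(plain, ap11, ap101) >= 0 & c(plain, ap11, ap101) <= 1))
})

test_that("mean_ap averages over classes", {
  expect_equal(mean_ap(0.73), 0.73)
  expect_equal(mean_ap(c(0.8, 0.6)), 0.7)
  expect_equal(mean_ap(rep(0.42, 7)), 0.42)
  expect_error(mean_ap(numeric(0)), "at least one")
})

test_that("metrics are scale-consistent between fractions and percent", {
  p <- 0.8123; r <- 0.7654
  expect_equal(f1_score(p, r) * 100, f1_score(p * 100, r * 100),
               tolerance = 1e-12)
})

test_that("stratified_report assigns the printed boundaries exactly", {
  cfg <- tiny_config(seed = 50)
  mk <- function(ptps, bad_chan = FALSE) {
    scr <- generate_background(cfg)
    scr$trial_stats$max_ptp <- ptps
    if (bad_chan) scr$bad_channel_mask[1] <- TRUE
    scr$trial_labels <- ptps > 500
    scr
  }
  # the two printed medians land in their categories; exact edges follow
  # the printed inequality directions
  ptps <- c(7744.4, 1057.3, 3000, 500, 499, rep(100, 5))
  scr <- mk(ptps, bad_chan = TRUE)
  rep <- stratified_report(list(scr), list(det(numeric(0), numeric(0))),
                           conf_thresh = 0.25)
  n <- rep$strata$n_trials
  names(n) <- rep$strata$stratum
  expect_equal(unname(n["severe"]), 1L)        # 7744.4
  expect_equal(unname(n["moderate"]), 2L)      # 1057.3 and exactly 3000
  # 500 exactly is NOT moderate; with a bad channel present it is
  # interference, as are all remaining clean trials
  expect_equal(unname(n["bad_channel_interference"]), 7L)
  expect_equal(sum(n), 10L)
  # without bad channels the low trials form the explicit clean stratum
  scr2 <- mk(ptps, bad_chan = FALSE)
  rep2 <- stratified_report(list(scr2), list(det(numeric(0), numeric(0))))
  n2 <- rep2$strata$n_trials
  names(n2) <- rep2$strata$stratum
  expect_equal(unname(n2["clean"]), 7L)
  expect_equal(unname(n2["bad_channel_interference"]), 0L)
})

test_that("stratified counts partition trials and score detections", {
  cfg <- tiny_config(seed = 51)
  scr <- generate_background(cfg)
  scr <- inject_artifact(scr, 2, calibrate_severity("emg", "severe", cfg))
  scr <- inject_artifact(scr, 7, calibrate_severity("eye_movement",
                                                    "moderate", cfg))
  scr$trial_labels <- scr$trial_stats$max_ptp > 500
  dets <- rbind(det(0.15, 0.9),   # hits trial 2 (severe)
                det(0.35, 0.8))   # false positive in a clean trial
  rep <- stratified_report(list(scr), list(dets))
  st <- rep$strata
  expect_equal(st$TP[st$stratum == "severe"], 1L)
  expect_equal(st$FN[st$stratum == "moderate"], 1L)
  expect_equal(st$FP[st$stratum == "clean"], 1L)
  expect_equal(sum(st$n_trials), 10L)
  expect_error(stratified_report(list(structure(list(trial_stats = NULL),
                                                class = "eeg_screen")),
                                 list(dets)), "trial_stats")
})

test_that("evaluate_detections combines matching, AP and operating P/R", {
  truth <- list(rbind(box_row(0.05), box_row(0.85)), box_row(0.45))
  dets <- list(rbind(det(0.05, 0.95), det(0.85, 0.9), det(0.55, 0.3)),
               det(0.45, 0.85))
  ev <- evaluate_detections(dets, truth)
  expect_equal(ev$counts$TP, 3L)
  expect_equal(ev$counts$FP, 1L)
  expect_equal(ev$precision, 0.75)
  expect_equal(ev$recall, 1)
  expect_equal(ev$map, ev$ap)
  expect_equal(ev$ap, 1)  # all truths ranked above the single FP
})
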