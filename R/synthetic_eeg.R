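# Synthetic multichannel ERP screens with calibrated artifacts.
#
# A "screen" is one model input: ten stimulus-locked trials of a
# multichannel recording (64-channel montage by default), with optional
# injected artifacts of four classes, optional bad channels, per-trial
# peak-to-peak statistics and context-adaptive bad-trial ground truth.
# The background is 1/f ("pink") noise plus a 10 Hz alpha component and a
# P300-like positive deflection at 300 ms on every trial.  Amplitudes are
# in microvolts throughout.

#' Severity band edges for peak-to-peak stratification
#'
#' Trials are graded by the maximum over channels of their peak-to-peak
#' amplitude: clean (<= 500), moderate (500, 3000], severe (> 3000).
#'
#' @param moderate_low lower edge of the moderate band, microvolts
#' @param severe_low lower edge of the severe band, microvolts
#' @return a `severity_bands` object
#' @export
severity_bands <- function(moderate_low = 500, severe_low = 3000) {
  if (!(moderate_low > 0 && severe_low > moderate_low))
    stop("need 0 < moderate_low < severe_low")
  structure(list(moderate_low = moderate_low, severe_low = severe_low),
            class = "severity_bands")
}

#' Band of a peak-to-peak value
#' @param ptp numeric vector of Max PTP values, microvolts
#' @param bands a [severity_bands()]
#' @return character vector: "clean", "moderate" or "severe"
#' @export
band_of_ptp <- function(ptp, bands = severity_bands()) {
  ifelse(ptp > bands$severe_low, "severe",
         ifelse(ptp > bands$moderate_low, "moderate", "clean"))
}

#' Generator configuration
#'
#' @param n_channels electrode count (64-channel montage by default)
#' @param sfreq sampling rate, Hz
#' @param trial_len trial epoch length, seconds
#' @param quality_level background quality in [0,1]; 1 is clean, lower
#'   values scale the background noise up (by `1 + 3 * (1 - quality)`)
#' @param erp_amplitude peak amplitude of the P300-like template, microvolts
#' @param noise_gain background noise scale (standard deviation), microvolts
#' @param seed integer seed, or NULL to use the ambient RNG state
#' @return a `gen_config` object (trials per screen is fixed at 10)
#' @export
gen_config <- function(n_channels = 64L, sfreq = 250, trial_len = 1.0,
                       quality_level = 1.0, erp_amplitude = 10,
                       noise_gain = 20, seed = NULL) {
  if (sfreq <= 0) stop("sfreq must be positive")
  if (trial_len <= 0) stop("trial_len must be positive")
  if (quality_level < 0 || quality_level > 1)
    stop("quality_level must lie in [0, 1]")
  if (n_channels < 1) stop("need at least one channel")
  structure(list(n_channels = as.integer(n_channels), sfreq = sfreq,
                 trial_len = trial_len, trials_per_screen = 10L,
                 quality_level = quality_level,
                 erp_amplitude = erp_amplitude, noise_gain = noise_gain,
                 seed = seed),
            class = "gen_config")
}

#' Artifact specification
#'
#' @param kind one of "signal_noise", "eye_movement", "emg", "movement"
#' @param channels integer indices of affected channels
#' @param onset artifact onset within the trial, seconds
#' @param duration artifact duration, seconds
#' @param amplitude peak-to-peak amplitude of the injected waveform on the
#'   most affected channel, microvolts (>= 0)
#' @return an `artifact_spec` object
#' @export
artifact_spec <- function(kind, channels, onset, duration, amplitude) {
  kinds <- c("signal_noise", "eye_movement", "emg", "movement")
  if (!kind %in% kinds)
    stop("kind must be one of: ", paste(kinds, collapse = ", "))
  if (duration <= 0) stop("duration must be positive")
  if (amplitude < 0) stop("amplitude must be non-negative")
  if (onset < 0) stop("onset must be non-negative")
  structure(list(kind = kind, channels = as.integer(channels),
                 onset = onset, duration = duration, amplitude = amplitude),
            class = "artifact_spec")
}

# 1/f-amplitude-shaped Gaussian noise, unit-ish scale
pink_noise <- function(n) {
  white <- stats::rnorm(n)
  sp <- stats::fft(white)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)              # mirrored frequency index
  sp <- sp / sqrt(f)
  x <- Re(stats::fft(sp, inverse = TRUE)) / n
  x / stats::sd(x)
}

erp_template <- function(config) {
  t <- seq(0, config$trial_len, length.out = n_samples(config))
  config$erp_amplitude * exp(-0.5 * ((t - 0.3) / 0.05)^2)
}

n_samples <- function(config) max(2L, round(config$sfreq * config$trial_len))

#' Generate an artifact-free screen
#'
#' Ten trials of 1/f background noise plus a 10 Hz alpha component and a
#' time-locked P300-like deflection on every channel.  Deterministic for a
#' fixed `config$seed`.
#'
#' @param config a [gen_config()]
#' @return an `eeg_screen`: list with `data` (channels x trials x samples,
#'   microvolts), `bad_channel_mask`, `trial_labels`, `injected`,
#'   `trial_stats`, and the generating `config`
#' @export
generate_background <- function(config = gen_config()) {
  stopifnot(inherits(config, "gen_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  C <- config$n_channels
  Tn <- config$trials_per_screen
  S <- n_samples(config)
  gain <- config$noise_gain * (1 + 3 * (1 - config$quality_level))
  erp <- erp_template(config)
  tt <- seq(0, config$trial_len, length.out = S)
  data <- array(0, c(C, Tn, S))
  for (tr in seq_len(Tn)) {
    for (ch in seq_len(C)) {
      x <- erp
      if (gain > 0) {
        phase <- stats::runif(1, 0, 2 * pi)
        x <- x + gain * pink_noise(S) +
          0.5 * gain * sin(2 * pi * 10 * tt + phase)
      }
      data[ch, tr, ] <- x
    }
  }
  scr <- structure(list(data = data,
                        bad_channel_mask = rep(FALSE, C),
                        trial_labels = rep(FALSE, Tn),
                        injected = list(),
                        trial_stats = NULL,
                        config = config),
                   class = "eeg_screen")
  scr$trial_stats <- compute_trial_stats(scr)
  scr
}

artifact_waveform <- function(spec, nch, L, sfreq) {
  base <- switch(spec$kind,
    signal_noise = stats::rnorm(L),
    eye_movement = (1 - cos(2 * pi * seq(0, 1, length.out = L))) / 2,
    emg = {
      w <- stats::rnorm(L)
      sp <- stats::fft(w)
      f <- (seq_len(L) - 1) * sfreq / L
      f <- pmin(f, sfreq - f)
      keep <- f >= 20 & f <= min(100, 0.45 * sfreq)
      if (!any(keep)) keep <- f >= 0.25 * sfreq * 0.5
      sp[!keep] <- 0
      Re(stats::fft(sp, inverse = TRUE)) / L
    },
    movement = {
      step_at <- L %/% 3
      c(rep(0, step_at), rep(1, L - step_at)) +
        0.5 * seq(0, 1, length.out = L)^2
    })
  rng <- max(base) - min(base)
  if (rng == 0) base <- c(rep(0, L - 1), 1)  # degenerate guard
  base <- base / (max(base) - min(base)) * spec$amplitude
  # per-channel weighting: eye movements decay away from the first listed
  # (frontal) channel; other kinds hit all listed channels equally
  wch <- if (spec$kind == "eye_movement" && nch > 1)
    seq(1, 0.5, length.out = nch) else rep(1, nch)
  outer(wch, base)
}

#' Inject an artifact into one trial
#'
#' Adds the spec's waveform to the listed channels within
#' `[onset, onset + duration]`; all other samples are untouched.  The
#' realized waveform is normalized so its peak-to-peak amplitude on the
#' most affected channel equals `spec$amplitude`.
#'
#' @param screen an `eeg_screen`
#' @param trial 1-based trial index
#' @param spec an [artifact_spec()]
#' @return the screen with updated data, `injected` record and stats
#' @export
inject_artifact <- function(screen, trial, spec) {
  stopifnot(inherits(screen, "eeg_screen"), inherits(spec, "artifact_spec"))
  cfg <- screen$config
  Tn <- dim(screen$data)[2]
  C <- dim(screen$data)[1]
  if (trial < 1 || trial > Tn) stop("trial index out of range")
  if (any(spec$channels < 1 | spec$channels > C))
    stop("artifact channels out of range")
  if (spec$onset + spec$duration > cfg$trial_len + 1e-9)
    stop("artifact window exceeds the trial length")
  S <- dim(screen$data)[3]
  i0 <- max(1L, 1L + floor(spec$onset * cfg$sfreq + 1e-9))
  i1 <- min(S, ceiling((spec$onset + spec$duration) * cfg$sfreq - 1e-9))
  L <- i1 - i0 + 1L
  if (L < 2L) stop("artifact window shorter than two samples")
  wf <- artifact_waveform(spec, length(spec$channels), L, cfg$sfreq)
  screen$data[spec$channels, trial, i0:i1] <-
    screen$data[spec$channels, trial, i0:i1] + wf
  screen$injected[[length(screen$injected) + 1L]] <-
    list(trial = as.integer(trial), spec = spec)
  screen$trial_stats <- compute_trial_stats(screen)
  screen
}

#' Per-trial Max PTP and Max STD
#'
#' For each trial, the maximum over non-bad channels of the per-channel
#' peak-to-peak amplitude (max - min) and of the per-channel standard
#' deviation.  Channels flagged in `bad_channel_mask` are excluded so they
#' cannot drive the severity statistic.
#'
#' @param screen an `eeg_screen`
#' @return data.frame with columns `max_ptp`, `max_std` (microvolts)
#' @export
compute_trial_stats <- function(screen) {
  stopifnot(inherits(screen, "eeg_screen"))
  good <- !screen$bad_channel_mask
  if (!any(good)) stop("all channels are marked bad; no statistics")
  d <- screen$data[good, , , drop = FALSE]
  Tn <- dim(d)[2]
  ptp <- vapply(seq_len(Tn), function(tr) {
    m <- d[, tr, , drop = FALSE]
    dim(m) <- c(dim(d)[1], dim(d)[3])
    max(apply(m, 1, function(x) max(x) - min(x)))
  }, 0)
  mstd <- vapply(seq_len(Tn), function(tr) {
    m <- d[, tr, , drop = FALSE]
    dim(m) <- c(dim(d)[1], dim(d)[3])
    max(apply(m, 1, stats::sd))
  }, 0)
  data.frame(max_ptp = ptp, max_std = mstd)
}

#' Artifact spec targeting a severity band
#'
#' Returns a specification whose injection drives the trial's Max PTP into
#' the requested band: severe (> 3000), moderate (500, 3000], or clean
#' (no super-threshold injection).  Amplitudes leave headroom so the band
#' holds for any background quality level.
#'
#' @param kind artifact kind (see [artifact_spec()])
#' @param band "clean", "moderate" or "severe"
#' @param config a [gen_config()]
#' @return an [artifact_spec()]
#' @export
calibrate_severity <- function(kind, band, config = gen_config()) {
  bands <- c("clean", "moderate", "severe")
  if (!band %in% bands)
    stop("band must be one of: ", paste(bands, collapse = ", "))
  amplitude <- switch(band, clean = 0, moderate = 1500, severe = 6000)
  C <- config$n_channels
  channels <- switch(kind,
    eye_movement = seq_len(min(8L, C)),
    emg = seq.int(max(1L, C - 7L), C),
    signal_noise = max(1L, C %/% 2L),
    movement = seq_len(C),
    stop("unknown artifact kind: ", kind))
  artifact_spec(kind, channels, onset = 0.2 * config$trial_len,
                duration = 0.5 * config$trial_len, amplitude = amplitude)
}

#' Generate a labeled dataset of screens
#'
#' Places randomized artifacts according to the band mix, optionally marks
#' 1-3 bad channels per screen, and assigns context-adaptive ground truth:
#' a trial is bad iff its Max PTP exceeds
#' `max(absolute_floor, k * median(clean-trial Max PTP of the screen))`.
#' Identical artifacts are therefore labeled bad on clean screens and
#' tolerated on noisy ones.
#'
#' @param config a [gen_config()]
#' @param n_screens number of screens (> 0)
#' @param mix named proportions for bands `clean`, `moderate`, `severe`;
#'   must sum to 1
#' @param quality_range range from which each screen's quality level is
#'   drawn uniformly
#' @param bad_channel_prob probability that a screen carries bad channels
#' @param absolute_floor,k parameters of the adaptive labeling rule
#' @param seed integer seed for the whole dataset
#' @return list of `eeg_screen`s; each carries `threshold` and `quality`
#' @export
make_screen_dataset <- function(config = gen_config(), n_screens,
                                mix = c(clean = 0.7, moderate = 0.15,
                                        severe = 0.15),
                                quality_range = c(1, 1),
                                bad_channel_prob = 0.3,
                                absolute_floor = 500, k = 3,
                                seed = config$seed) {
  if (n_screens <= 0) stop("n_screens must be positive")
  if (abs(sum(mix) - 1) > 1e-6) stop("mix proportions must sum to 1")
  if (!all(names(mix) %in% c("clean", "moderate", "severe")))
    stop("mix must be named with clean/moderate/severe")
  if (!is.null(seed)) set.seed(seed)
  kinds <- c("signal_noise", "eye_movement", "emg", "movement")
  screens <- vector("list", n_screens)
  for (i in seq_len(n_screens)) {
    cfg <- config
    cfg$seed <- NULL
    cfg$quality_level <- stats::runif(1, quality_range[1], quality_range[2])
    scr <- generate_background(cfg)
    C <- cfg$n_channels
    if (stats::runif(1) < bad_channel_prob) {
      nbad <- sample(1:3, 1)
      bad <- sample(C, nbad)
      scr$bad_channel_mask[bad] <- TRUE
      # bad electrodes carry persistent moderate-level noise in all trials
      for (ch in bad) {
        amp <- stats::runif(1, 200, 600)
        scr$data[ch, , ] <- scr$data[ch, , ] +
          amp * matrix(stats::rnorm(prod(dim(scr$data)[2:3])),
                       dim(scr$data)[2])
      }
    }
    bands <- sample(names(mix), cfg$trials_per_screen, replace = TRUE,
                    prob = mix)
    for (tr in seq_len(cfg$trials_per_screen)) {
      if (bands[tr] == "clean") next
      kind <- sample(kinds, 1)
      spec <- calibrate_severity(kind, bands[tr], cfg)
      spec$amplitude <- spec$amplitude * stats::runif(1, 0.9, 1.2)
      spec$onset <- stats::runif(1, 0, 0.4) * cfg$trial_len
      spec$duration <- stats::runif(1, 0.3, 0.55) * cfg$trial_len
      if (kind %in% c("signal_noise", "emg")) {
        n_ch <- sample(seq(min(4L, C), min(12L, C)), 1)
        start <- sample(C - n_ch + 1L, 1)
        spec$channels <- seq.int(start, start + n_ch - 1L)
      }
      scr <- inject_artifact(scr, tr, spec)
    }
    scr$trial_stats <- compute_trial_stats(scr)
    injected_trials <- vapply(scr$injected, function(e) e$trial, 0L)
    clean_ptp <- scr$trial_stats$max_ptp[
      setdiff(seq_len(cfg$trials_per_screen), injected_trials)]
    med <- if (length(clean_ptp)) stats::median(clean_ptp) else 0
    thr <- max(absolute_floor, k * med)
    scr$threshold <- thr
    scr$quality <- cfg$quality_level
    scr$trial_labels <- scr$trial_stats$max_ptp > thr
    screens[[i]] <- scr
  }
  screens
}
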