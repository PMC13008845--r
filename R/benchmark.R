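# Benchmarks exercising the context-adaptive labeling rule, and the
# ablation harness that trains and evaluates the four detector
# configurations under one call.

#' Adaptive-tolerance benchmark screens
#'
#' Half the screens have clean backgrounds (quality near 1), half have
#' noisy backgrounds (quality near 0); both halves receive artifacts from
#' the same severity mix. Under the adaptive ground-truth rule the
#' moderate artifacts are labeled bad on the clean screens and tolerated
#' on the noisy ones, so a detector can only be precise here by reading
#' global signal quality.
#'
#' @param config a [gen_config()]
#' @param n_screens total screens (half clean, half noisy)
#' @param mix severity mix applied to both halves
#' @param seed dataset seed
#' @return list of `eeg_screen`s, clean and noisy interleaved
#' @export
make_adaptive_benchmark <- function(config = gen_config(), n_screens,
                                    mix = c(clean = 0.55, moderate = 0.3,
                                            severe = 0.15),
                                    seed = 0L) {
  n_clean <- ceiling(n_screens / 2)
  n_noisy <- n_screens - n_clean
  clean <- make_screen_dataset(config, n_clean, mix = mix,
                               quality_range = c(0.9, 1),
                               bad_channel_prob = 0.2, seed = seed)
  noisy <- make_screen_dataset(config, max(1, n_noisy), mix = mix,
                               quality_range = c(0, 0.1),
                               bad_channel_prob = 0.2, seed = seed + 1L)
  out <- vector("list", n_screens)
  ci <- ni <- 1L
  for (i in seq_len(n_screens)) {
    if (i %% 2L == 1L && ci <= n_clean) {
      out[[i]] <- clean[[ci]]; ci <- ci + 1L
    } else {
      out[[i]] <- noisy[[ni]]; ni <- ni + 1L
    }
  }
  out
}

#' Train and evaluate the ablation grid under one command
#'
#' Builds each configuration, trains it on the same split with the same
#' recipe and seed, and reports test precision, recall, mAP@0.5 and F1.
#'
#' @param screens list of `eeg_screen`s
#' @param input_size render size (divisible by 32)
#' @param width_multiple detector width (reduced widths train quickly)
#' @param tc a [train_config()]
#' @param configs named list of [detector_config()]s; defaults to the four
#'   ablation experiments
#' @param split train/val/test proportions
#' @return list with `results` (data.frame) and `models`
#' @export
run_ablation <- function(screens, input_size = 320L, width_multiple = 0.125,
                         tc = train_config(), configs = NULL,
                         split = c(0.7, 0.15, 0.15)) {
  if (is.null(configs))
    configs <- ablation_configs(width_multiple = width_multiple,
                                input_size = as.integer(input_size))
  samples <- build_detection_dataset(screens, input_size = input_size)
  n <- length(samples)
  set.seed(tc$seed)
  ord <- sample(n)
  ntr <- max(1L, round(split[1] * n))
  nva <- max(1L, round(split[2] * n))
  tr <- samples[ord[seq_len(ntr)]]
  va <- samples[ord[ntr + seq_len(min(nva, n - ntr))]]
  te_idx <- ord[setdiff(seq_len(n), seq_len(ntr + nva))]
  te <- if (length(te_idx)) samples[te_idx] else va
  results <- list()
  models <- list()
  for (nm in names(configs)) {
    set.seed(tc$seed)
    model <- build_model(configs[[nm]])
    fit <- train_model(model, tr, va, tc)
    ev <- eval_model(fit$model, te, conf_thresh = tc$conf_thresh,
                     iou_thresh = tc$iou_thresh)
    results[[nm]] <- data.frame(experiment = nm, precision = ev$precision,
                                recall = ev$recall, map = ev$map,
                                f1 = ev$f1)
    models[[nm]] <- fit$model
  }
  list(results = do.call(rbind, results), models = models,
       splits = list(train = ord[seq_len(ntr)],
                     val = ord[ntr + seq_len(min(nva, n - ntr))],
                     test = te_idx))
}
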