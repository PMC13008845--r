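# Screen dataset serialization: one binary array + one JSON sidecar per
# screen (format version 1).  The binary file holds the raw data array as
# little-endian doubles in (channel, trial, sample) column-major order;
# everything else (labels, stats, mask, artifact specs, generator settings)
# lives in the sidecar.

#' Save screens to a directory
#' @param screens list of `eeg_screen`s
#' @param dir output directory (created)
#' @return invisibly, the directory
#' @export
save_screens <- function(screens, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(screens)) {
    scr <- screens[[i]]
    stub <- file.path(dir, sprintf("screen_%04d", i))
    con <- file(paste0(stub, ".bin"), "wb")
    writeBin(as.numeric(scr$data), con, size = 8, endian = "little")
    close(con)
    side <- list(
      format_version = 1L,
      dim = dim(scr$data),
      bad_channel_mask = scr$bad_channel_mask,
      trial_labels = scr$trial_labels,
      trial_stats = scr$trial_stats,
      threshold = scr$threshold,
      quality = scr$quality,
      injected = lapply(scr$injected, function(e)
        c(list(trial = e$trial), unclass(e$spec))),
      config = unclass(scr$config))
    jsonlite::write_json(side, paste0(stub, ".json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
  }
  invisible(dir)
}

#' Load screens saved by [save_screens()]
#' @param dir dataset directory
#' @return list of `eeg_screen`s
#' @export
load_screens <- function(dir) {
  sides <- sort(list.files(dir, pattern = "^screen_\\d+\\.json$",
                           full.names = TRUE))
  lapply(sides, function(sf) {
    side <- jsonlite::read_json(sf, simplifyVector = TRUE)
    if (is.null(side$format_version) || side$format_version != 1L)
      stop("unsupported screen format in ", sf)
    bin <- sub("\\.json$", ".bin", sf)
    d <- as.integer(side$dim)
    con <- file(bin, "rb")
    data <- readBin(con, "numeric", n = prod(d), size = 8,
                    endian = "little")
    close(con)
    dim(data) <- d
    cfg <- side$config
    config <- gen_config(cfg$n_channels, cfg$sfreq, cfg$trial_len,
                         cfg$quality_level, cfg$erp_amplitude,
                         cfg$noise_gain,
                         if (is.null(cfg$seed)) NULL else cfg$seed)
    injected <- list()
    if (length(side$injected)) {
      inj <- side$injected
      injected <- lapply(seq_len(nrow(inj)), function(i) {
        row <- inj[i, ]
        list(trial = as.integer(row$trial),
             spec = artifact_spec(row$kind, unlist(row$channels),
                                  row$onset, row$duration, row$amplitude))
      })
    }
    structure(list(data = data,
                   bad_channel_mask = side$bad_channel_mask,
                   trial_labels = side$trial_labels,
                   injected = injected,
                   trial_stats = as.data.frame(side$trial_stats),
                   config = config,
                   threshold = side$threshold,
                   quality = side$quality),
              class = "eeg_screen")
  })
}
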