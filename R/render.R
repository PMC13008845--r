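# Waveform-screen rendering and YOLO label IO.
#
# Screens are drawn the way ERP review tools display them: channels stacked
# top-to-bottom as rows, the ten trials side by side left-to-right,
# adjacent trials separated by dashed dark-blue vertical lines, previously
# identified bad channels in gray.  The plot area is the full image (no
# axes or margins), so bad-trial bounding boxes have exact geometry: a bad
# trial t (0-based) spans cx = (t + 0.5)/10, w = 1/10, full height.

#' Renderer configuration
#'
#' @param width,height output raster size in pixels
#' @param waveform_color,bad_channel_color,separator_color,background_color
#'   RGB triplets in [0,1]
#' @param line_width nominal line width, pixels (1 supported)
#' @param amplitude_clip microvolts mapped to a channel-row half-height;
#'   amplitudes are soft-compressed (tanh) so large artifacts saturate
#'   instead of escaping their row
#' @return a `render_config` object
#' @export
render_config <- function(width = 640L, height = 640L,
                          waveform_color = c(0.05, 0.25, 0.05),
                          bad_channel_color = c(0.6, 0.6, 0.6),
                          separator_color = c(0.05, 0.05, 0.55),
                          background_color = c(1, 1, 1),
                          line_width = 1L, amplitude_clip = 200) {
  if (width <= 0 || height <= 0) stop("image dimensions must be positive")
  if (amplitude_clip <= 0) stop("amplitude_clip must be positive")
  chk <- function(x) length(x) == 3 && all(x >= 0 & x <= 1)
  if (!all(vapply(list(waveform_color, bad_channel_color, separator_color,
                       background_color), chk, TRUE)))
    stop("colors must be RGB triplets in [0,1]")
  structure(list(width = as.integer(width), height = as.integer(height),
                 waveform_color = waveform_color,
                 bad_channel_color = bad_channel_color,
                 separator_color = separator_color,
                 background_color = background_color,
                 line_width = as.integer(line_width),
                 amplitude_clip = amplitude_clip),
            class = "render_config")
}

#' Render a screen to an RGB raster
#'
#' Pure function of (screen, config): same inputs give identical rasters.
#'
#' @param screen an `eeg_screen`
#' @param config a [render_config()]
#' @return numeric array `height x width x 3` in [0,1]
#' @export
render_screen <- function(screen, config = render_config()) {
  stopifnot(inherits(screen, "eeg_screen"), inherits(config, "render_config"))
  H <- config$height; W <- config$width
  C <- dim(screen$data)[1]
  Tn <- dim(screen$data)[2]
  S <- dim(screen$data)[3]
  img <- array(rep(config$background_color, each = H * W), c(H, W, 3))
  # dashed separators: 6 px on / 6 px off, 1 px wide
  for (t in seq_len(Tn - 1)) {
    x <- round(W * t / Tn)
    on <- which((seq_len(H) - 1) %% 12 < 6)
    img[on, x, 1] <- config$separator_color[1]
    img[on, x, 2] <- config$separator_color[2]
    img[on, x, 3] <- config$separator_color[3]
  }
  row_h <- H / C
  col_w <- W / Tn
  clip <- config$amplitude_clip
  half <- row_h / 2
  for (ch in seq_len(C)) {
    col <- if (screen$bad_channel_mask[ch]) config$bad_channel_color
           else config$waveform_color
    mid <- (ch - 0.5) * row_h
    r_lo <- floor((ch - 1) * row_h) + 1L
    r_hi <- max(r_lo, ceiling(ch * row_h))
    for (tr in seq_len(Tn)) {
      v <- screen$data[ch, tr, ]
      y <- mid - tanh(v / clip) * (half - 0.5)
      xs <- (tr - 1) * col_w + (seq_len(S) - 0.5) / S * col_w
      cpp_draw_polyline(img, H, W, xs, y, col, r_lo, r_hi)
    }
  }
  img
}

#' Ground-truth boxes for the bad trials of a screen
#'
#' One full-height box per bad trial: `cx = (t + 0.5)/10`, `w = 1/10`,
#' `cy = 0.5`, `h = 1` in normalized image coordinates.
#'
#' @param screen an `eeg_screen`
#' @return matrix with columns `class`, `cx`, `cy`, `w`, `h` (0 rows when
#'   no trial is bad); class is always 0 ("bad")
#' @export
boxes_for_bad_trials <- function(screen) {
  stopifnot(inherits(screen, "eeg_screen"))
  Tn <- length(screen$trial_labels)
  bad <- which(screen$trial_labels)
  m <- matrix(0, length(bad), 5,
              dimnames = list(NULL, c("class", "cx", "cy", "w", "h")))
  if (length(bad)) {
    m[, "cx"] <- (bad - 0.5) / Tn
    m[, "cy"] <- 0.5
    m[, "w"] <- 1 / Tn
    m[, "h"] <- 1
  }
  m
}

#' Write YOLO-format labels
#'
#' One line per box: `class cx cy w h`, space-separated, 6-decimal fixed
#' point.  Reading inverts writing exactly at that precision.
#'
#' @param boxes matrix as from [boxes_for_bad_trials()]
#' @param path output text file
#' @export
write_labels <- function(boxes, path) {
  lines <- if (nrow(boxes)) {
    apply(boxes, 1, function(b)
      sprintf("%d %.6f %.6f %.6f %.6f", as.integer(b[1]), b[2], b[3],
              b[4], b[5]))
  } else character()
  writeLines(lines, path)
  invisible(path)
}

#' Read YOLO-format labels
#' @param path label text file
#' @return box matrix with columns `class`, `cx`, `cy`, `w`, `h`
#' @export
read_labels <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  m <- matrix(0, length(lines), 5,
              dimnames = list(NULL, c("class", "cx", "cy", "w", "h")))
  for (i in seq_along(lines)) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(parts))
    if (length(parts) != 5 || anyNA(vals))
      stop(sprintf("malformed label line %d in %s", i, path))
    m[i, ] <- vals
  }
  m
}

#' Write an RGB raster as binary PPM (P6)
#' @param img array `H x W x 3` in [0,1]
#' @param path output file ending in `.ppm`
#' @export
write_ppm <- function(img, path) {
  d <- dim(img)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("P6", paste(d[2], d[1]), "255"), con, sep = "\n")
  px <- aperm(img, c(3, 2, 1))  # stream order: RGB within pixel, row-major
  writeBin(as.integer(round(255 * px)), con, size = 1)
  invisible(path)
}

#' Read a binary PPM (P6) written by [write_ppm()]
#' @param path input file
#' @return array `H x W x 3` in [0,1]
#' @export
read_ppm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  # parse the header byte-wise: readLines would read past it
  hdr <- character(0)
  tok <- ""
  while (length(hdr) < 4) {
    ch <- readChar(con, 1, useBytes = TRUE)
    if (length(ch) == 0) stop("truncated PPM header")
    if (ch %in% c(" ", "\t", "\n", "\r")) {
      if (nzchar(tok)) hdr <- c(hdr, tok)
      tok <- ""
    } else {
      tok <- paste0(tok, ch)
    }
  }
  if (hdr[1] != "P6") stop("not a P6 PPM file")
  wh <- as.integer(hdr[2:3])
  if (hdr[4] != "255") stop("only 8-bit PPM supported")
  raw <- readBin(con, "integer", n = 3 * wh[1] * wh[2], size = 1,
                 signed = FALSE)
  px <- array(raw / 255, c(3, wh[1], wh[2]))
  aperm(px, c(3, 2, 1))
}

#' Write an RGB raster as PNG via the grDevices device (when available)
#' @inheritParams write_ppm
#' @export
write_png <- function(img, path) {
  if (!capabilities("png")) stop("this R build has no png device")
  d <- dim(img)
  grDevices::png(path, width = d[2], height = d[1])
  op <- graphics::par(mar = c(0, 0, 0, 0))
  graphics::plot.new()
  graphics::rasterImage(img, 0, 0, 1, 1, interpolate = FALSE)
  graphics::par(op)
  grDevices::dev.off()
  invisible(path)
}

#' Render screens to an image + label dataset directory
#'
#' Writes `screen_XXXX.ppm` and matching `.txt` label files plus a
#' `manifest.yaml` listing the train/val/test split (70/15/15 by default,
#' assigned in order after a seeded shuffle).
#'
#' @param screens list of `eeg_screen`s
#' @param out_dir output directory (created)
#' @param config a [render_config()]
#' @param split proportions for train/val/test
#' @param seed shuffle seed
#' @return invisibly, a data.frame of files and split assignment
#' @export
render_dataset <- function(screens, out_dir, config = render_config(),
                           split = c(train = 0.7, val = 0.15, test = 0.15),
                           seed = 0L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(screens)
  set.seed(seed)
  ord <- sample(n)
  n_train <- round(split[["train"]] * n)
  n_val <- round(split[["val"]] * n)
  assign <- rep("test", n)
  assign[ord[seq_len(n_train)]] <- "train"
  if (n_val > 0)
    assign[ord[n_train + seq_len(min(n_val, n - n_train))]] <- "val"
  files <- character(n)
  for (i in seq_len(n)) {
    stub <- sprintf("screen_%04d", i)
    img <- render_screen(screens[[i]], config)
    write_ppm(img, file.path(out_dir, paste0(stub, ".ppm")))
    write_labels(boxes_for_bad_trials(screens[[i]]),
                 file.path(out_dir, paste0(stub, ".txt")))
    files[i] <- stub
  }
  manifest <- list(version = 1L, n = n,
                   train = files[assign == "train"],
                   val = files[assign == "val"],
                   test = files[assign == "test"])
  yaml_write(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(data.frame(file = files, split = assign,
                       stringsAsFactors = FALSE))
}
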