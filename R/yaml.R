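# Minimal YAML subset reader/writer for run configuration and manifests.
#
# Supported: one level of `key: value` mappings where a value is a scalar
# (number, logical, string), an inline list `[a, b, c]`, or a block list of
# `- item` lines.  This covers everything the package emits; it is not a
# general YAML parser (the environment provides none).

#' Write a flat named list as YAML
#' @param x named list of scalars / vectors
#' @param path output file
#' @export
yaml_write <- function(x, path) {
  fmt_scalar <- function(v) {
    if (is.logical(v)) return(ifelse(v, "true", "false"))
    if (is.numeric(v)) return(format(v, scientific = FALSE, trim = TRUE))
    as.character(v)
  }
  lines <- character(0)
  for (nm in names(x)) {
    v <- x[[nm]]
    if (length(v) == 1L) {
      lines <- c(lines, paste0(nm, ": ", fmt_scalar(v)))
    } else if (length(v) == 0L) {
      lines <- c(lines, paste0(nm, ": []"))
    } else {
      lines <- c(lines, paste0(nm, ":"),
                 paste0("  - ", vapply(v, fmt_scalar, "")))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read the YAML subset written by [yaml_write()]
#' @param path input file
#' @return named list; numerics and logicals are converted
#' @export
yaml_read <- function(path) {
  parse_scalar <- function(s) {
    s <- trimws(s)
    if (s %in% c("true", "True", "yes")) return(TRUE)
    if (s %in% c("false", "False", "no")) return(FALSE)
    n <- suppressWarnings(as.numeric(s))
    if (!is.na(n)) return(n)
    gsub('^"|"$', "", s)
  }
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  out <- list()
  key <- NULL
  for (ln in lines) {
    if (grepl("^\\s*-\\s", ln)) {
      if (is.null(key)) stop("list item before any key in ", path)
      out[[key]] <- c(out[[key]], parse_scalar(sub("^\\s*-\\s*", "", ln)))
    } else if (grepl("^[^:]+:", ln)) {
      key <- trimws(sub(":.*$", "", ln))
      val <- sub("^[^:]+:\\s*", "", ln)
      if (trimws(val) == "") {
        out[key] <- list(NULL)
      } else if (grepl("^\\[", trimws(val))) {
        items <- strsplit(gsub("^\\[|\\]$", "", trimws(val)), ",")[[1]]
        out[[key]] <- if (length(items))
          unlist(lapply(items, parse_scalar)) else character(0)
      } else {
        out[[key]] <- parse_scalar(val)
      }
    } else {
      stop("cannot parse line in ", path, ": ", ln)
    }
  }
  out
}
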