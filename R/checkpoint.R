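# Checkpoints: versioned RDS with the config, all parameter values and the
# batch-norm running statistics, keyed by the deterministic module paths.

collect_buffers <- function(m, prefix = "") {
  out <- list()
  if (!is.null(m$buffers))
    out[[prefix]] <- list(rm = m$buffers$rm, rv = m$buffers$rv)
  for (nm in names(m$children))
    out <- c(out, collect_buffers(m$children[[nm]],
                                  if (nzchar(prefix)) paste0(prefix, ".", nm)
                                  else nm))
  out
}

restore_buffers <- function(m, buffers, prefix = "") {
  if (!is.null(m$buffers) && !is.null(buffers[[prefix]])) {
    m$buffers$rm <- buffers[[prefix]]$rm
    m$buffers$rv <- buffers[[prefix]]$rv
  }
  for (nm in names(m$children))
    restore_buffers(m$children[[nm]], buffers,
                    if (nzchar(prefix)) paste0(prefix, ".", nm) else nm)
  invisible(NULL)
}

#' Save a model checkpoint
#' @param model a built detector
#' @param path output `.rds` file
#' @export
save_checkpoint <- function(model, path) {
  params <- module_params(model)
  saveRDS(list(format_version = 1L,
               cfg = model$cfg,
               params = lapply(params, function(p) p$v),
               buffers = collect_buffers(model)),
          path)
  invisible(path)
}

#' Load a model checkpoint
#' @param path file written by [save_checkpoint()]
#' @return a rebuilt detector with restored weights and statistics
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (is.null(ck$format_version) || ck$format_version != 1L)
    stop("unsupported checkpoint format")
  model <- build_model(ck$cfg)
  params <- module_params(model)
  stopifnot(identical(names(params), names(ck$params)))
  for (nm in names(params)) params[[nm]]$v <- ck$params[[nm]]
  restore_buffers(model, ck$buffers)
  model
}

# deep copy of the learnable state (used for best-checkpoint tracking)
snapshot_state <- function(model) {
  list(params = lapply(module_params(model), function(p) p$v),
       buffers = collect_buffers(model))
}

restore_state <- function(model, st) {
  params <- module_params(model)
  for (nm in names(params)) params[[nm]]$v <- st$params[[nm]]
  restore_buffers(model, st$buffers)
  invisible(model)
}
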