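#' Read and write configurations as YAML
#'
#' Configurations are plain named lists, so they round-trip through YAML.
#' `read_sim_config()` applies [sim_config()] defaults to any field the file
#' omits and validates the result; `read_pipeline_config()` does the same via
#' [pipeline_config()], resolving a nested `sim:` block with
#' [sim_config()]. `write_config()` writes either kind.
#'
#' @param path Path to a YAML file.
#' @param config A `sim_config` or `pipeline_config`.
#' @return The validated configuration object (readers) or `path`,
#'   invisibly (writer).
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(sim_config)))
  if (length(unknown) > 0) {
    abort(paste0("Unknown sim config field(s): ", paste(unknown, collapse = ", ")))
  }
  do.call(sim_config, vals)
}

#' @rdname read_sim_config
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$sim)) vals$sim <- do.call(sim_config, vals$sim)
  unknown <- setdiff(names(vals), names(formals(pipeline_config)))
  if (length(unknown) > 0) {
    abort(paste0("Unknown pipeline config field(s): ", paste(unknown, collapse = ", ")))
  }
  do.call(pipeline_config, vals)
}

#' @rdname read_sim_config
#' @export
write_config <- function(config, path) {
  out <- unclass(config)
  if (!is.null(out$sim)) out$sim <- unclass(out$sim)
  yaml::write_yaml(out, path)
  invisible(path)
}
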