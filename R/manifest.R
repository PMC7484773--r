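#' Write a run manifest alongside analysis outputs
#'
#' Records, as JSON, everything needed to reproduce a run bit-exactly: the
#' step name, the resolved configuration, every seed used, the input and
#' output paths, the package version and a timestamp.
#'
#' @param path destination path for the manifest JSON.
#' @param step name of the analysis step.
#' @param config resolved configuration (any list coercible to JSON).
#' @param seeds named list or vector of the seeds used.
#' @param inputs,outputs character vectors of file paths.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, step, config = list(), seeds = list(),
                               inputs = character(0), outputs = character(0)) {
  manifest <- list(
    step = step,
    config = config,
    seeds = seeds,
    inputs = inputs,
    outputs = outputs,
    package_version = as.character(utils::packageVersion("seqmonitor")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
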