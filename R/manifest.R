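#' Write a run manifest
#'
#' Every pipeline output directory carries exactly one `manifest.json`
#' recording what produced it: a snapshot of the resolved configuration, the
#' geometry hash, the seeds in play, per-stage wall-clock timings and the
#' package version. Re-running a stochastic stage with the recorded seed
#' reproduces its outputs bit-identically.
#'
#' @param out_dir Output directory (created if missing).
#' @param stage Name of the pipeline stage (e.g. `"simulate"`).
#' @param config A list snapshot of the stage's resolved configuration.
#' @param geometry_hash Hash of the geometry in use, or `NULL`.
#' @param seed Integer seed, or `NULL` for deterministic stages.
#' @param timings Named numeric vector of stage timings in seconds.
#' @return The manifest path, invisibly.
#' @export
write_manifest <- function(out_dir, stage, config = list(),
                           geometry_hash = NULL, seed = NULL,
                           timings = c()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(
    list(stage = stage, config = config, geometry_hash = geometry_hash,
         seed = seed, timings_s = as.list(timings),
         package_version = as.character(utils::packageVersion("slnf"))),
    path, auto_unbox = TRUE, digits = 10, null = "null")
  invisible(path)
}
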