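#' Write a run manifest into an output directory
#'
#' Records tool version, config hash, input file hashes, the seed and a
#' timestamp, giving every output directory a provenance record.
#'
#' @param dir output directory (created if needed).
#' @param inputs named or unnamed character vector of input file paths to
#'   hash.
#' @param seed seed used by the run, if any.
#' @param config_hash hash of the governing config, if any.
#' @return path of the written `manifest.json`, invisibly.
#' @export
write_manifest <- function(dir, inputs = character(), seed = NULL,
                           config_hash = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  inputs <- inputs[file.exists(inputs)]
  hashes <- setNames(vapply(inputs, hash_file, character(1)),
                     basename(inputs))
  manifest <- list(
    tool = "scfapath",
    version = as.character(packageVersion("scfapath")),
    config_hash = config_hash,
    input_hashes = as.list(hashes),
    seed = seed,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, null = "null",
                       pretty = TRUE)
  invisible(path)
}

#' Read a run manifest
#' @param dir directory containing `manifest.json` (or the file itself).
#' @return manifest as a list.
#' @export
read_manifest <- function(dir) {
  path <- if (dir.exists(dir)) file.path(dir, "manifest.json") else dir
  if (!file.exists(path)) stop_scfa("no manifest at %s", path)
  jsonlite::read_json(path)
}
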