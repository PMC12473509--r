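#' Save and load window archives
#'
#' Window archives hold a list of window samples (frames/landmarks or the
#' five aligned input tensors), the label manifest and the generating or
#' preprocessing configuration, serialized with R's native RDS format.  The
#' synthetic generator and the preprocessing path emit the same structure, so
#' the two are interchangeable downstream.  [write_manifest_csv()] exports
#' the label manifest as plain CSV.
#'
#' @param data a `"facephys_data"` object (or compatible list with `windows`
#'   and `manifest`).
#' @param path archive file path (`.rds`).
#' @return `load_windows` returns the archive contents.
#' @export
save_windows <- function(data, path) {
  stopifnot(!is.null(data$windows), !is.null(data$manifest))
  saveRDS(data, path)
  invisible(path)
}

#' @rdname save_windows
#' @export
load_windows <- function(path) readRDS(path)

#' @rdname save_windows
#' @param csv_path output CSV path for the manifest.
#' @export
write_manifest_csv <- function(data, csv_path) {
  write.csv(data$manifest, csv_path, row.names = FALSE)
  invisible(csv_path)
}
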