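#' Read or write event tables (FCS or CSV)
#'
#' CSV dialect: comma separator, mandatory header row of channel names, `.`
#' decimal mark, UTF-8, one row per event.
#'
#' @param path File path.
#' @param format `"fcs"` or `"csv"`; default guessed from the extension.
#' @return `read_events()`: list with `events` tibble and `metadata` list.
#' @export
read_events <- function(path, format = c("auto", "fcs", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.fcs$", path, ignore.case = TRUE)) "fcs" else "csv"
  }
  if (format == "fcs") return(read_fcs(path))
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  if (anyDuplicated(names(df))) {
    abort(sprintf("duplicate channel names in %s", path))
  }
  events <- set_transform_state(tibble::as_tibble(df), "raw")
  list(events = events, metadata = list(format = "csv", path = path))
}

#' @rdname read_events
#' @param events Event tibble.
#' @param ... Passed to [write_fcs()] for the FCS format.
#' @export
write_events <- function(events, path, format = c("auto", "fcs", "csv"), ...) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.fcs$", path, ignore.case = TRUE)) "fcs" else "csv"
  }
  if (format == "fcs") return(write_fcs(events, path, ...))
  write.csv(events, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read/write a spillover matrix as CSV
#'
#' Square matrix with channel labels as header row and first column.
#' Convention: entry `[i, j]` is the fraction of dye `j`'s true signal
#' observed in detector `i` (unit diagonal).
#'
#' @param path CSV file.
#' @return `read_spillover()` returns the matrix with dimnames.
#' @export
read_spillover <- function(path) {
  df <- read.csv(path, check.names = FALSE, row.names = 1)
  S <- as.matrix(df)
  spillover_matrix(S, rownames(S))
}

#' @rdname read_spillover
#' @param spill Spillover matrix.
#' @export
write_spillover <- function(spill, path) {
  write.csv(as.data.frame(spill), path, row.names = TRUE)
  invisible(path)
}

#' Write a ground-truth manifest as JSON
#'
#' @param manifest A `cg_manifest` from [simulate_sample()].
#' @param path Output path.
#' @export
write_manifest <- function(manifest, path) {
  eff <- manifest$effect
  out <- list(
    labels = manifest$labels,
    counts = manifest$counts,
    seed = manifest$seed,
    n_events = manifest$n_events,
    beads_added = manifest$beads_added,
    bead_recovery = manifest$bead_recovery,
    cofactor = manifest$cofactor,
    effect = list(
      group = eff$group, hemisphere = eff$hemisphere,
      microglia_fraction_multiplier = eff$microglia_fraction_multiplier,
      channel_shifts = as.list(eff$channel_shifts),
      correlation_matrix = eff$correlation_matrix))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
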