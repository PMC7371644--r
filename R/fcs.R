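# Minimal FCS 3.0/3.1 reader and FCS 3.1 float writer.
#
# Scope: list-mode ($MODE=L) files with $DATATYPE F (float32) or D (float64)
# read support, float32 write. This covers instrument exports re-saved by
# analysis software and our own round-trips; integer data types and FCS 2.0
# are out of scope.

fcs_delim <- "/"

#' Write an event table as FCS 3.1
#'
#' List mode, `$DATATYPE=F` (float32), little-endian. Channel names go to
#' `$PnN` and, when `stain_names` is given, stain labels to `$PnS`.
#'
#' @param events Event tibble (numeric channel columns).
#' @param path Output path.
#' @param stain_names Optional named character vector, channel -> stain
#'   label, written as `$PnS`.
#' @param keywords Optional named character vector of extra TEXT keywords.
#' @return `path`, invisibly.
#' @export
write_fcs <- function(events, path, stain_names = NULL, keywords = NULL) {
  channels <- event_channels(events)
  if (anyDuplicated(channels)) abort("duplicate channel names")
  X <- as.matrix(events[channels])
  storage.mode(X) <- "double"
  n_par <- ncol(X)
  n_tot <- nrow(X)
  data_len <- 4L * n_par * n_tot

  kw <- c(
    "$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0",
    "$BEGINSTEXT" = "0", "$ENDSTEXT" = "0",
    "$BYTEORD" = "1,2,3,4", "$DATATYPE" = "F", "$MODE" = "L",
    "$NEXTDATA" = "0",
    "$PAR" = as.character(n_par), "$TOT" = as.character(n_tot))
  for (i in seq_len(n_par)) {
    rng <- max(262144, 2^ceiling(log2(max(abs(X[, i]), 1) + 1)))
    kw[sprintf("$P%dB", i)] <- "32"
    kw[sprintf("$P%dE", i)] <- "0,0"
    kw[sprintf("$P%dN", i)] <- channels[i]
    kw[sprintf("$P%dR", i)] <- format(rng, scientific = FALSE)
    if (!is.null(stain_names) && channels[i] %in% names(stain_names)) {
      kw[sprintf("$P%dS", i)] <- stain_names[[channels[i]]]
    }
  }
  if (!is.null(keywords)) kw[names(keywords)] <- keywords

  build_text <- function(kw) {
    paste0(fcs_delim,
           paste0(names(kw), fcs_delim, unname(kw), fcs_delim, collapse = ""))
  }
  # data offsets depend on TEXT length; pad the offset keywords to fixed width
  kw["$BEGINDATA"] <- sprintf("%12d", 0)
  kw["$ENDDATA"] <- sprintf("%12d", 0)
  text_len <- nchar(build_text(kw), type = "bytes")
  text_start <- 58L # header: 6 version + 4 spaces + 6 x 8-char offsets
  data_start <- text_start + text_len
  kw["$BEGINDATA"] <- sprintf("%12d", data_start)
  kw["$ENDDATA"] <- sprintf("%12d", data_start + data_len - 1L)
  text <- build_text(kw)
  stopifnot(nchar(text, type = "bytes") == text_len)

  header <- sprintf("FCS3.1    %8d%8d%8d%8d%8d%8d",
                    text_start, text_start + text_len - 1L,
                    data_start, data_start + data_len - 1L, 0L, 0L)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(text, con, eos = NULL)
  writeBin(as.vector(t(X)), con, size = 4, endian = "little")
  invisible(path)
}

parse_fcs_text <- function(raw_text) {
  txt <- rawToChar(raw_text)
  delim <- substr(txt, 1, 1)
  parts <- strsplit(substring(txt, 2), delim, fixed = TRUE)[[1]]
  if (length(parts) < 2) abort("FCS TEXT segment is empty or malformed")
  if (length(parts) %% 2 == 1) parts <- parts[-length(parts)]
  keys <- parts[seq(1, length(parts), by = 2)]
  vals <- parts[seq(2, length(parts), by = 2)]
  setNames(vals, toupper(trimws(keys)))
}

#' Read an FCS 3.0/3.1 file
#'
#' Supports list-mode files with float32/float64 data. Channel labels are
#' canonicalized: the stain name `$PnS` is preferred over the short name
#' `$PnN` when present; the mapping is returned in the metadata.
#'
#' @param path FCS file.
#' @return List with `events` (tibble) and `metadata` (list: the TEXT
#'   keywords plus `channel_map`).
#' @export
read_fcs <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))
  header <- rawToChar(readBin(con, "raw", 58))
  version <- substr(header, 1, 6)
  if (!version %in% c("FCS3.0", "FCS3.1")) {
    abort(sprintf("unsupported FCS version '%s'", version))
  }
  off <- suppressWarnings(as.integer(substring(
    header, 10 + 8 * (0:5) + 1, 10 + 8 * (1:6))))
  if (any(is.na(off[1:2]))) abort("malformed FCS header offsets")
  text_start <- off[1]; text_end <- off[2]

  seek(con, text_start)
  kw <- parse_fcs_text(readBin(con, "raw", text_end - text_start + 1))

  need <- function(key) {
    if (!key %in% names(kw)) abort(sprintf("FCS missing required keyword %s", key))
    kw[[key]]
  }
  if (toupper(need("$MODE")) != "L") abort("only list-mode ($MODE=L) FCS supported")
  dtype <- toupper(need("$DATATYPE"))
  if (!dtype %in% c("F", "D")) {
    abort(sprintf("unsupported $DATATYPE '%s' (only F/D)", dtype))
  }
  n_par <- as.integer(need("$PAR"))
  n_tot <- as.integer(need("$TOT"))
  byteord <- need("$BYTEORD")
  endian <- if (byteord %in% c("1,2,3,4")) "little" else
    if (byteord %in% c("4,3,2,1")) "big" else
      abort(sprintf("unsupported $BYTEORD '%s'", byteord))

  data_start <- off[3]
  data_end <- off[4]
  if (is.na(data_start) || data_start == 0) {
    data_start <- as.integer(need("$BEGINDATA"))
    data_end <- as.integer(need("$ENDDATA"))
  }
  size <- if (dtype == "F") 4L else 8L
  expected <- size * n_par * n_tot
  if (!is.na(data_end) && data_end > 0 &&
      (data_end - data_start + 1L) < expected) {
    abort("FCS data segment shorter than $PAR x $TOT declares")
  }
  seek(con, data_start)
  vals <- readBin(con, "numeric", n = n_par * n_tot, size = size,
                  endian = endian)
  if (length(vals) < n_par * n_tot) abort("truncated FCS data segment")
  X <- matrix(vals, ncol = n_par, byrow = TRUE)

  pnn <- vapply(seq_len(n_par), function(i) {
    k <- sprintf("$P%dN", i)
    if (!k %in% names(kw)) abort(sprintf("FCS missing required keyword %s", k))
    kw[[k]]
  }, character(1))
  pns <- vapply(seq_len(n_par), function(i) {
    k <- sprintf("$P%dS", i)
    if (k %in% names(kw)) kw[[k]] else NA_character_
  }, character(1))
  canonical <- ifelse(is.na(pns) | pns == "", pnn, pns)
  if (anyDuplicated(canonical)) {
    abort(sprintf("duplicate channel labels after canonicalization: %s",
                  paste(canonical[duplicated(canonical)], collapse = ", ")))
  }
  colnames(X) <- canonical
  events <- tibble::as_tibble(X)
  events <- set_transform_state(events, "raw")
  list(events = events,
       metadata = list(keywords = kw, version = version,
                       channel_map = tibble::tibble(
                         pnn = pnn, pns = pns, canonical = canonical)))
}
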