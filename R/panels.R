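#' Channel vocabulary and staining panels
#'
#' Event tables are plain tibbles with one row per event and one column per
#' channel. Channel names are canonical labels: scatter (`FSC_A`, `FSC_H`,
#' `SSC_A`), the viability dye (`Viability`), the counting-bead flag channel
#' (`Bead`) and the surface markers. Two staining panels are analysed
#' separately: the pro-inflammatory (M1) panel carries CD32 and CD86 next to
#' the three identification markers (CD45, CD11b/c, P2y12); the
#' anti-inflammatory (M2) panel carries CD200R, RT1B and CD163.
#'
#' @param name Panel label, `"M1"` or `"M2"`.
#' @return `panel_def()` returns a tibble with columns `channel` and `class`
#'   (`scatter`, `viability`, `bead` or `marker`).
#' @examples
#' panel_def("M1")
#' panel_markers("M2")
#' @export
panel_def <- function(name = c("M1", "M2")) {
  name <- match.arg(name)
  tibble::tibble(
    channel = c("FSC_A", "FSC_H", "SSC_A", "Viability", "Bead",
                panel_markers(name)),
    class = c("scatter", "scatter", "scatter", "viability", "bead",
              rep("marker", length(panel_markers(name))))
  )
}

#' @rdname panel_def
#' @export
panel_markers <- function(name = c("M1", "M2")) {
  name <- match.arg(name)
  id <- c("CD45", "CD11bc", "P2y12")
  if (name == "M1") c(id, "CD32", "CD86") else c(id, "CD200R", "RT1B", "CD163")
}

#' @rdname panel_def
#' @export
identification_markers <- function() c("CD45", "CD11bc", "P2y12")

#' @rdname panel_def
#' @param channels Character vector of channel names.
#' @return `channel_class()` returns the class label of each channel;
#'   unknown names are classed `"marker"` so user-defined markers work.
#' @export
channel_class <- function(channels) {
  known <- c(FSC_A = "scatter", FSC_H = "scatter", SSC_A = "scatter",
             Viability = "viability", Bead = "bead")
  out <- unname(known[channels])
  out[is.na(out)] <- "marker"
  out
}

#' @rdname panel_def
#' @param events Event tibble.
#' @export
fluorescence_channels <- function(events) {
  ch <- event_channels(events)
  ch[channel_class(ch) != "scatter"]
}

#' List the channel columns of an event tibble
#'
#' Non-numeric columns and bookkeeping columns (`sample_id`, `event_id`,
#' metadata labels) are not channels.
#'
#' @param events Event tibble.
#' @return Character vector of channel column names.
#' @export
event_channels <- function(events) {
  reserved <- c("sample_id", "event_id", "animal_id", "group", "hemisphere",
                "panel", "population")
  nm <- names(events)
  nm[!nm %in% reserved & vapply(events, is.numeric, logical(1))]
}

#' Transform-state bookkeeping
#'
#' Event tables move forward through `raw -> compensated -> transformed`;
#' the state is carried in the `"transform_state"` attribute (absent means
#' `"raw"`).
#'
#' @param events Event tibble.
#' @return A string: `"raw"`, `"compensated"` or `"transformed"`.
#' @export
transform_state <- function(events) {
  attr(events, "transform_state") %||% "raw"
}

set_transform_state <- function(events, state) {
  prev <- transform_state(events)
  order <- c(raw = 1L, compensated = 2L, transformed = 3L)
  if (order[[state]] < order[[prev]]) {
    abort(sprintf("transform state may only move forward (%s -> %s refused)",
                  prev, state))
  }
  attr(events, "transform_state") <- state
  events
}

#' The four experimental conditions
#'
#' @return Tibble with `group` (`sham`/`CCI`) and `hemisphere`
#'   (`ipsilateral`/`contralateral`).
#' @export
condition_grid <- function() {
  tidyr::expand_grid(group = c("sham", "CCI"),
                     hemisphere = c("ipsilateral", "contralateral"))
}
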