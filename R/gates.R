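#' Gate constructors
#'
#' Four gate geometries over one or two channels:
#' * `gate_rectangle()` — closed box on two channels (boundary included);
#'   infinite bounds allowed.
#' * `gate_polygon()` — point-in-polygon by the even-odd rule, boundary
#'   points included.
#' * `gate_threshold()` — one channel; `direction = "above"` keeps strictly
#'   greater values (the "+" convention for positive populations),
#'   `"below"` keeps the complement (`<=`). The threshold value may be fixed
#'   or found at run time by the valley policy (minimum of the kernel
#'   density between its two largest modes), falling back to `fallback` with
#'   a warning when no valley exists.
#' * `gate_ratio_band()` — keeps events whose `channels[2] / channels[1]`
#'   ratio lies in `[lo, hi]`; events with non-positive denominator are
#'   excluded.
#'
#' @param name Gate label.
#' @param channels Channel name(s).
#' @param xlim,ylim Rectangle bounds (ordered, closed).
#' @param vertices Polygon vertex matrix (>= 3 rows, columns x and y).
#' @param value Threshold value (or `NULL` with `policy = "valley"`).
#' @param direction `"above"` or `"below"`.
#' @param policy `"fixed"` or `"valley"`.
#' @param fallback Fallback threshold when valley finding fails.
#' @param band Length-2 ratio band `c(lo, hi)` with `lo < hi`.
#' @return A `cg_gate` list.
#' @export
gate_rectangle <- function(name, channels, xlim, ylim) {
  stopifnot(length(channels) == 2, length(xlim) == 2, length(ylim) == 2)
  if (xlim[1] > xlim[2] || ylim[1] > ylim[2]) {
    abort("rectangle bounds must be ordered (lo <= hi)")
  }
  structure(list(name = name, kind = "rectangle", channels = channels,
                 xlim = xlim, ylim = ylim), class = "cg_gate")
}

#' @rdname gate_rectangle
#' @export
gate_polygon <- function(name, channels, vertices) {
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 3) abort("polygon needs at least 3 vertices")
  # collinearity check: all cross products zero means degenerate polygon
  v1 <- diff(vertices[, 1]); v2 <- diff(vertices[, 2])
  cross <- v1[-length(v1)] * v2[-1] - v1[-1] * v2[-length(v2)]
  if (all(abs(cross) < 1e-12)) abort("polygon vertices are collinear")
  structure(list(name = name, kind = "polygon", channels = channels,
                 vertices = vertices), class = "cg_gate")
}

#' @rdname gate_rectangle
#' @export
gate_threshold <- function(name, channels, value = NULL,
                           direction = c("above", "below"),
                           policy = c("fixed", "valley"), fallback = NULL) {
  direction <- match.arg(direction)
  policy <- match.arg(policy)
  if (policy == "fixed" && is.null(value)) {
    abort("fixed threshold gates need a `value`")
  }
  structure(list(name = name, kind = "threshold", channels = channels[1],
                 value = value, direction = direction, policy = policy,
                 fallback = fallback %||% value), class = "cg_gate")
}

#' @rdname gate_rectangle
#' @export
gate_ratio_band <- function(name, channels, band) {
  stopifnot(length(channels) == 2, length(band) == 2)
  if (band[1] >= band[2]) abort("ratio band needs lo < hi")
  structure(list(name = name, kind = "ratio_band", channels = channels,
                 band = band), class = "cg_gate")
}

# Even-odd point-in-polygon with boundary inclusion.
points_in_polygon <- function(x, y, vertices) {
  n <- nrow(vertices)
  vx <- vertices[, 1]; vy <- vertices[, 2]
  inside <- rep(FALSE, length(x))
  on_edge <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    xi <- vx[i]; yi <- vy[i]; xj <- vx[j]; yj <- vy[j]
    # boundary: point within the segment's bounding box and collinear
    cross <- (x - xi) * (yj - yi) - (y - yi) * (xj - xi)
    seg <- abs(cross) < 1e-9 * pmax(1, abs(xj - xi) + abs(yj - yi)) &
      x >= pmin(xi, xj) - 1e-12 & x <= pmax(xi, xj) + 1e-12 &
      y >= pmin(yi, yj) - 1e-12 & y <= pmax(yi, yj) + 1e-12
    on_edge <- on_edge | seg
    crosses <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | on_edge
}

#' Find the valley between the two largest modes of a distribution
#'
#' Kernel density estimate; returns the location of the density minimum
#' between the two highest local maxima, or `NA` when the distribution has
#' fewer than two modes.
#'
#' @param x Numeric vector.
#' @param n Density grid size.
#' @return Threshold value or `NA_real_`.
#' @export
valley_threshold <- function(x, n = 512) {
  x <- x[is.finite(x)]
  if (length(x) < 10) return(NA_real_)
  d <- density(x, n = n)
  y <- d$y
  is_max <- which(diff(sign(diff(y))) == -2) + 1L
  if (length(is_max) < 2) return(NA_real_)
  top2 <- sort(is_max[order(y[is_max], decreasing = TRUE)][1:2])
  between <- seq(top2[1], top2[2])
  valley <- between[which.min(y[between])]
  # a genuine valley must dip well below both modes; KDE wiggles on a
  # unimodal distribution do not
  if (y[valley] > 0.5 * min(y[top2])) return(NA_real_)
  d$x[valley]
}

resolve_threshold <- function(gate, values) {
  if (gate$policy == "fixed") return(gate$value)
  thr <- valley_threshold(values)
  if (is.na(thr)) {
    if (is.null(gate$fallback)) {
      abort(sprintf("gate '%s': no valley found and no fallback threshold",
                    gate$name))
    }
    warn(sprintf("gate '%s': no valley found; using fallback threshold %g",
                 gate$name, gate$fallback))
    thr <- gate$fallback
  }
  thr
}

#' Apply one gate to an event table
#'
#' @param events Event tibble.
#' @param gate A `cg_gate`.
#' @param parent_mask Logical vector (length = events); the returned mask is
#'   always a subset of it. Valley thresholds are computed from parent
#'   events only.
#' @return Logical membership vector.
#' @export
apply_gate <- function(events, gate, parent_mask = NULL) {
  n <- nrow(events)
  if (is.null(parent_mask)) parent_mask <- rep(TRUE, n)
  if (length(parent_mask) != n) {
    abort("`parent_mask` length must equal the event count")
  }
  missing <- setdiff(gate$channels, names(events))
  if (length(missing)) {
    abort(sprintf("gate '%s': channel(s) %s not in event table",
                  gate$name, paste(missing, collapse = ", ")))
  }
  if (n == 0) return(logical(0))
  mask <- switch(
    gate$kind,
    rectangle = {
      x <- events[[gate$channels[1]]]; y <- events[[gate$channels[2]]]
      x >= gate$xlim[1] & x <= gate$xlim[2] &
        y >= gate$ylim[1] & y <= gate$ylim[2]
    },
    polygon = points_in_polygon(events[[gate$channels[1]]],
                                events[[gate$channels[2]]], gate$vertices),
    threshold = {
      v <- events[[gate$channels[1]]]
      thr <- resolve_threshold(gate, v[parent_mask])
      if (gate$direction == "above") v > thr else v <= thr
    },
    ratio_band = {
      den <- events[[gate$channels[1]]]; num <- events[[gate$channels[2]]]
      ratio <- num / den
      den > 0 & ratio >= gate$band[1] & ratio <= gate$band[2]
    },
    abort(sprintf("unknown gate kind '%s'", gate$kind)))
  mask & parent_mask
}

#' Singlet selection by pulse-geometry ratio
#'
#' Keeps events whose `FSC_H / FSC_A` ratio lies in `band`; aggregates
#' (doublets) have roughly doubled area but not height, so their ratio falls
#' below the band. Events with `FSC_A <= 0` are excluded.
#'
#' @param events Event tibble with `FSC_A` and `FSC_H`.
#' @param band Ratio band, default `c(0.75, 1.10)`.
#' @return Logical vector.
#' @export
singlet_mask <- function(events, band = c(0.75, 1.10)) {
  apply_gate(events, gate_ratio_band("singlets", c("FSC_A", "FSC_H"), band))
}

#' Live-cell selection on the viability dye
#'
#' Live cells are dye-negative: events at or below the threshold are kept.
#' By default the threshold is placed at the valley between the live and
#' dead dye modes, falling back to `fallback` (with a warning) when the
#' distribution is unimodal.
#'
#' @param events Event tibble.
#' @param dye_channel Viability channel name.
#' @param threshold Fixed threshold (overrides valley finding).
#' @param fallback Fallback for the valley policy.
#' @return Logical vector.
#' @export
viability_mask <- function(events, dye_channel = "Viability",
                           threshold = NULL, fallback = 1.8) {
  gate <- if (is.null(threshold)) {
    gate_threshold("live", dye_channel, direction = "below",
                   policy = "valley", fallback = fallback)
  } else {
    gate_threshold("live", dye_channel, value = threshold,
                   direction = "below")
  }
  apply_gate(events, gate)
}
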