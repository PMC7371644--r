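#' Construct and validate a spillover matrix
#'
#' Convention (matching instrument compensation wizards): `S[i, j]` is the
#' fraction of dye `j`'s true signal observed in detector `i`, so observed
#' events satisfy `observed = true %*% t(S)` row-wise, and compensation
#' solves that linear system. The diagonal must be 1 and the matrix
#' invertible; the condition number is stored for diagnostics.
#'
#' @param values Square numeric matrix.
#' @param channels Fluorescence channel labels (row = detector, column =
#'   dye, same ordering).
#' @return A `cg_spillover` matrix with dimnames and a `condition_number`
#'   attribute.
#' @examples
#' S <- spillover_matrix(matrix(c(1, 0, 0.1, 1), 2), c("CD45", "CD11bc"))
#' @export
spillover_matrix <- function(values, channels = colnames(values)) {
  if (!is.matrix(values) || nrow(values) != ncol(values)) {
    abort("spillover must be a square matrix")
  }
  if (is.null(channels)) abort("spillover channels must be named")
  if (any(abs(diag(values) - 1) > 1e-12)) {
    abort("spillover matrix must have a unit diagonal")
  }
  dimnames(values) <- list(channels, channels)
  kappa <- kappa(values, exact = TRUE)
  if (!is.finite(kappa) || kappa > 1e12) {
    abort(sprintf("spillover matrix is singular or near-singular (condition number %.3g)",
                  kappa))
  }
  structure(values, condition_number = kappa, class = c("cg_spillover", "matrix"))
}

#' Apply spillover compensation to an event table
#'
#' The fluorescence submatrix is unmixed by solving
#' `observed = compensated %*% t(S)`; scatter channels are untouched and
#' negative compensated values are retained (clipping would bias MFI
#' estimates). Moves the transform state from `raw` to `compensated`.
#'
#' @param events Raw event tibble.
#' @param spill [spillover_matrix()] over a subset of the table's
#'   fluorescence channels. The identity matrix leaves the table unchanged.
#' @return Compensated event tibble.
#' @export
apply_compensation <- function(events, spill) {
  if (transform_state(events) != "raw") {
    abort("compensation must be applied to raw events")
  }
  ch <- rownames(spill)
  missing <- setdiff(ch, event_channels(events))
  if (length(missing)) {
    abort(sprintf("spillover references absent channels: %s",
                  paste(missing, collapse = ", ")))
  }
  if (any(channel_class(ch) == "scatter")) {
    abort("spillover must only reference fluorescence channels")
  }
  X <- as.matrix(events[ch])
  comp <- t(solve(unclass(spill), t(X)))
  out <- events
  out[ch] <- tibble::as_tibble(comp)
  set_transform_state(out, "compensated")
}

#' Arcsinh-transform the fluorescence channels of an event table
#'
#' Each fluorescence value `x` becomes `asinh(x / cofactor)`; scatter
#' channels stay linear. The transform is strictly monotone, so median
#' ordering between samples is preserved. Records the transform in the
#' table's state.
#'
#' @param events Raw or compensated event tibble.
#' @param cofactor Positive cofactor (default 150, conventional for
#'   photomultiplier fluorescence); may be a named vector per channel.
#' @param channels Channels to transform; defaults to all fluorescence
#'   channels.
#' @return Transformed event tibble.
#' @export
transform_intensities <- function(events, cofactor = 150,
                                  channels = fluorescence_channels(events)) {
  if (transform_state(events) == "transformed") {
    abort("events are already transformed")
  }
  if (any(cofactor <= 0)) abort("`cofactor` must be positive")
  cf <- if (length(cofactor) == 1) {
    setNames(rep(cofactor, length(channels)), channels)
  } else {
    if (!all(channels %in% names(cofactor))) {
      abort("named `cofactor` must cover all transformed channels")
    }
    cofactor[channels]
  }
  out <- events
  for (ch in channels) out[[ch]] <- asinh_transform(events[[ch]], cf[[ch]])
  if (transform_state(out) == "raw") out <- set_transform_state(out, "compensated")
  out <- set_transform_state(out, "transformed")
  attr(out, "transform") <- list(method = "arcsinh", cofactor = cf)
  out
}

#' Compensate and transform every sample of a cohort
#'
#' @param cohort `cg_cohort` tibble.
#' @param spill Optional spillover matrix applied to each sample.
#' @param cofactor Arcsinh cofactor.
#' @return Cohort with transformed `events`.
#' @export
prepare_cohort <- function(cohort, spill = NULL, cofactor = 150) {
  cohort$events <- purrr::map(cohort$events, function(ev) {
    if (!is.null(spill)) ev <- apply_compensation(ev, spill)
    transform_intensities(ev, cofactor = cofactor)
  })
  cohort
}
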