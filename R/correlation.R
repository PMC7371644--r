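#' Pearson correlation matrix over marker columns
#'
#' @param events Event tibble or matrix (events x markers), >= 4 rows.
#' @param markers Columns to use; defaults to all numeric channels.
#' @return Symmetric correlation matrix with unit diagonal; zero-variance
#'   markers give `NA` rows/columns and a warning (they are excluded from
#'   downstream screens).
#' @export
pearson_matrix <- function(events, markers = NULL) {
  X <- if (is.matrix(events)) events else {
    markers <- markers %||% event_channels(events)
    as.matrix(events[markers])
  }
  if (!is.null(markers)) X <- X[, markers, drop = FALSE]
  if (nrow(X) < 4) abort("need at least 4 events for a correlation matrix")
  zero_var <- apply(X, 2, function(v) var(v) == 0 || !is.finite(var(v)))
  if (any(zero_var)) {
    warn(sprintf("zero-variance marker(s) excluded: %s",
                 paste(colnames(X)[zero_var], collapse = ", ")))
  }
  R <- suppressWarnings(cor(X, method = "pearson"))
  R[zero_var, ] <- NA_real_
  R[, zero_var] <- NA_real_
  diag(R) <- ifelse(zero_var, NA_real_, 1)
  R
}

#' Fisher z-transform of a correlation coefficient
#'
#' `z = atanh(rho)`; odd-symmetric and variance-stabilising.
#'
#' @param rho Correlation(s) with `|rho| < 1`.
#' @param clamp If `TRUE`, values at or beyond +-1 are clamped to
#'   `+-(1 - 1e-12)` with a warning instead of erroring.
#' @return z value(s).
#' @export
fisher_z <- function(rho, clamp = FALSE) {
  bad <- is.finite(rho) & abs(rho) >= 1
  if (any(bad)) {
    if (!clamp) abort("|rho| >= 1: Fisher z undefined (set clamp = TRUE to clamp)")
    warn("clamping |rho| >= 1 to 1 - 1e-12")
    rho[bad] <- sign(rho[bad]) * (1 - 1e-12)
  }
  atanh(rho)
}

#' Cohen's q effect size for a difference between two correlations
#'
#' `q = |atanh(rho1) - atanh(rho2)|`: the absolute difference on the Fisher
#' z scale.
#'
#' @param rho1,rho2 Correlations with absolute value < 1.
#' @param clamp Passed to [fisher_z()].
#' @return Non-negative effect size.
#' @examples
#' cohens_q(0.68, 0.30) # 0.5196
#' @export
cohens_q <- function(rho1, rho2, clamp = FALSE) {
  abs(fisher_z(rho1, clamp) - fisher_z(rho2, clamp))
}

#' Two-sample test for a difference between independent correlations
#'
#' Standard Fisher-z normal test:
#' `z = (atanh(rho1) - atanh(rho2)) / sqrt(1/(n1-3) + 1/(n2-3))`, with the
#' one-sided `"greater"` alternative (rho1 > rho2) by default.
#'
#' @param rho1,rho2 Sample correlations.
#' @param n1,n2 Sample sizes (> 3).
#' @param alternative `"greater"` or `"two.sided"`.
#' @param clamp Passed to [fisher_z()].
#' @return Tibble with `z_statistic` and `p_value`.
#' @export
correlation_difference_test <- function(rho1, n1, rho2, n2,
                                        alternative = c("greater", "two.sided"),
                                        clamp = FALSE) {
  alternative <- match.arg(alternative)
  if (any(c(n1, n2) <= 3)) abort("both sample sizes must exceed 3")
  z <- (fisher_z(rho1, clamp) - fisher_z(rho2, clamp)) /
    sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  p <- if (alternative == "greater") pnorm(z, lower.tail = FALSE) else
    2 * pnorm(abs(z), lower.tail = FALSE)
  tibble::tibble(z_statistic = z, p_value = p)
}

#' Differential marker-correlation screen against sham
#'
#' Pearson correlations per unordered marker pair in both event sets,
#' Cohen's q on the Fisher-z scale, one-sided Fisher-z tests for
#' injury-greater-than-sham, and Benjamini-Hochberg FDR across all pairs in
#' the comparison. The headline summary is the fraction of pairs whose
#' injury correlation is significantly *higher* than sham.
#'
#' @param injury_events,sham_events Microglia-gated event tibbles (>= 4
#'   rows each), transformed scale.
#' @param markers Markers to correlate (>= 2); default all shared numeric
#'   channels.
#' @param q FDR level (default 0.01).
#' @return A `cg_corr_diff` list: `pairs` tibble (one row per unordered
#'   pair: correlations, Cohen's q, z, p, adjusted p,
#'   `fdr_significant_higher`), `fraction_significantly_higher`, and
#'   `q_matrix` (symmetric Cohen's-q heat-map matrix, zero diagonal).
#' @export
differential_correlation_screen <- function(injury_events, sham_events,
                                            markers = NULL, q = 0.01) {
  markers <- markers %||% intersect(event_channels(injury_events),
                                    event_channels(sham_events))
  if (length(markers) < 2) abort("need at least 2 markers")
  n1 <- nrow(injury_events); n2 <- nrow(sham_events)
  if (n1 < 4 || n2 < 4) abort("need at least 4 events in each condition")
  R1 <- pearson_matrix(injury_events, markers)
  R2 <- pearson_matrix(sham_events, markers)

  idx <- which(upper.tri(R1), arr.ind = TRUE)
  pairs <- tibble::tibble(
    marker_1 = markers[idx[, 1]], marker_2 = markers[idx[, 2]],
    rho_injury = R1[idx], rho_sham = R2[idx],
    n_injury = n1, n_sham = n2)
  usable <- !is.na(pairs$rho_injury) & !is.na(pairs$rho_sham)
  test <- correlation_difference_test(
    pairs$rho_injury[usable], n1, pairs$rho_sham[usable], n2, clamp = TRUE)
  pairs$cohens_q <- NA_real_
  pairs$cohens_q[usable] <- cohens_q(pairs$rho_injury[usable],
                                     pairs$rho_sham[usable], clamp = TRUE)
  pairs$z_statistic <- NA_real_
  pairs$p_value <- NA_real_
  pairs$z_statistic[usable] <- test$z_statistic
  pairs$p_value[usable] <- test$p_value
  fdr <- bh_fdr(pairs$p_value, q)
  pairs$p_adjusted <- fdr$p_adjusted
  pairs$fdr_significant_higher <- fdr$rejected &
    pairs$rho_injury > pairs$rho_sham

  qm <- matrix(0, length(markers), length(markers),
               dimnames = list(markers, markers))
  qm[idx] <- pairs$cohens_q
  qm[idx[, c(2, 1), drop = FALSE]] <- pairs$cohens_q

  structure(list(
    pairs = pairs,
    fraction_significantly_higher =
      sum(pairs$fdr_significant_higher, na.rm = TRUE) / nrow(pairs),
    q_matrix = qm, fdr_level = q), class = "cg_corr_diff")
}

#' @export
print.cg_corr_diff <- function(x, ...) {
  cat(sprintf(
    "<cg_corr_diff> %d marker pairs, %.0f%% significantly higher (FDR %.2g)\n",
    nrow(x$pairs), 100 * x$fraction_significantly_higher, x$fdr_level))
  print(x$pairs)
  invisible(x)
}

#' Differential correlation across a gated cohort
#'
#' Runs [differential_correlation_screen()] per panel and hemisphere, pooled
#' microglia events, injured vs sham.
#'
#' @param cohort Gated cohort.
#' @param q FDR level.
#' @param balance_animals If `TRUE`, each animal contributes equally many
#'   events (downsampled without replacement to the smallest animal, seeded)
#'   so one animal cannot dominate the pooled correlation.
#' @param seed Seed for the balancing downsample.
#' @return Tibble with columns `panel`, `hemisphere`,
#'   `fraction_significantly_higher` and list column `screen`.
#' @export
cohort_correlation <- function(cohort, q = 0.01, balance_animals = FALSE,
                               seed = 1L) {
  pool <- function(sub) {
    evs <- sub$microglia
    if (balance_animals) {
      n_min <- min(vapply(evs, nrow, integer(1)))
      evs <- purrr::imap(evs, function(ev, i) {
        idx <- downsample_events(ev, n_min, seed = seed + i)
        ev[idx, , drop = FALSE]
      })
    }
    dplyr::bind_rows(evs)
  }
  families <- tidyr::expand_grid(panel = unique(cohort$panel),
                                 hemisphere = unique(cohort$hemisphere))
  purrr::pmap_dfr(families, function(panel, hemisphere) {
    sub <- cohort[cohort$panel == panel & cohort$hemisphere == hemisphere, ]
    inj <- pool(sub[sub$group == "CCI", ])
    sham <- pool(sub[sub$group == "sham", ])
    scr <- differential_correlation_screen(
      inj[panel_markers(panel)], sham[panel_markers(panel)], q = q)
    tibble::tibble(
      panel = panel, hemisphere = hemisphere,
      fraction_significantly_higher = scr$fraction_significantly_higher,
      screen = list(scr))
  })
}
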