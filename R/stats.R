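#' Fluorescence-intensity summary of a gated population
#'
#' MFI as the median (default; robust) or arithmetic mean of a channel's
#' values. The even-length median uses the usual midpoint convention.
#'
#' @param values Non-empty numeric vector.
#' @param statistic `"median"` or `"mean"`.
#' @return The summary value.
#' @export
compute_mfi <- function(values, statistic = c("median", "mean")) {
  statistic <- match.arg(statistic)
  if (length(values) == 0) abort("cannot summarise an empty intensity vector")
  if (statistic == "median") median(values) else mean(values)
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two samples. `U` is the number of (x, y) pairs
#' with `x > y`, counting ties as 1/2 (midranks). The p-value is exact (full
#' enumeration of the rank distribution) when the smaller sample has at most
#' 8 observations and there are no ties, otherwise a normal approximation
#' with tie and continuity corrections is used. When the pooled data are
#' constant the test is degenerate and returns `p = 1` with a warning.
#'
#' @param x,y Numeric vectors (length >= 1).
#' @param alternative `"two.sided"`, `"greater"` (x tends larger) or
#'   `"less"`.
#' @return Tibble with `U`, `p_value`, `n_x`, `n_y`, `method`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6), alternative = "less") # p = 0.05
#' @export
mann_whitney_u <- function(x, y,
                           alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(x) < 1 || length(y) < 1) abort("both samples must be non-empty")
  pooled <- c(x, y)
  ties <- anyDuplicated(pooled) > 0
  if (length(unique(pooled)) == 1) {
    warn("pooled data are constant; Mann-Whitney U is degenerate (p = 1)")
    return(tibble::tibble(U = length(x) * length(y) / 2, p_value = 1,
                          n_x = length(x), n_y = length(y),
                          method = "degenerate"))
  }
  exact <- min(length(x), length(y)) <= 8 && !ties
  ht <- suppressWarnings(wilcox.test(x, y, alternative = alternative,
                                     exact = exact, correct = TRUE))
  tibble::tibble(U = unname(ht$statistic), p_value = ht$p.value,
                 n_x = length(x), n_y = length(y),
                 method = if (exact) "exact" else "normal_approx")
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up procedure: with ordered p-values `p_(1) <= ... <= p_(m)`, reject
#' all hypotheses up to the largest `k` with `p_(k) <= k q / m`. Adjusted
#' p-values are the usual step-up minima, so rejection is `adjusted <= q`.
#' `NA` p-values are carried through unadjusted and never rejected.
#'
#' @param p_values Vector of p-values in `[0, 1]` (NAs allowed).
#' @param q Target false discovery rate in (0, 1).
#' @return Tibble with `p_value`, `p_adjusted`, `rejected`.
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  if (q <= 0 || q >= 1) abort("`q` must lie in (0, 1)")
  if (length(p_values) == 0) {
    return(tibble::tibble(p_value = numeric(), p_adjusted = numeric(),
                          rejected = logical()))
  }
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  adj <- p.adjust(p_values, method = "BH")
  tibble::tibble(p_value = p_values, p_adjusted = adj,
                 rejected = !is.na(adj) & adj <= q)
}

#' Per-marker differential screen of a gated cohort
#'
#' For each panel and hemisphere, pools microglia-gated events across
#' animals within condition and tests injured vs sham per parameter with the
#' Mann-Whitney U test, controlling the Benjamini-Hochberg FDR within each
#' (panel, hemisphere) comparison family. Scatter parameters (FSC-A, SSC-A)
#' are screened alongside the fluorescence markers. Events are the
#' statistical unit, reproducing the event-pooling of conventional
#' cytometry bioinformatics; for a replication-honest alternative see
#' `unit = "animal"`, which tests per-animal MFIs instead (weak at n = 3
#' animals, but free of pseudoreplication).
#'
#' @param cohort Gated cohort from [gate_cohort()].
#' @param q FDR level.
#' @param statistic MFI statistic used for the direction call and the
#'   animal-level mode.
#' @param parameters Parameters to screen; default scatter plus the panel
#'   markers.
#' @param unit `"event"` (pooled events, default) or `"animal"`.
#' @return Tidy tibble, one row per (panel, hemisphere, parameter):
#'   `U`, `p_value`, `p_adjusted`, `fdr_significant`, `direction`
#'   (`up`/`down`/`none`), MFIs of both groups and event counts. A condition
#'   with zero gated events yields `NA` statistics and a `note`.
#' @export
marker_screen <- function(cohort, q = 0.05,
                          statistic = c("median", "mean"),
                          parameters = NULL,
                          unit = c("event", "animal")) {
  statistic <- match.arg(statistic)
  unit <- match.arg(unit)
  if (!"microglia" %in% names(cohort)) {
    abort("`cohort` must be gated first (see gate_cohort())")
  }
  scale_note <- if (all(purrr::map_chr(cohort$events, transform_state) ==
                        "transformed")) "arcsinh" else "linear"

  families <- tidyr::expand_grid(panel = unique(cohort$panel),
                                 hemisphere = unique(cohort$hemisphere))
  res <- purrr::pmap_dfr(families, function(panel, hemisphere) {
    params <- parameters %||% c("FSC_A", "SSC_A", panel_markers(panel))
    sub <- cohort[cohort$panel == panel & cohort$hemisphere == hemisphere, ]
    rows <- purrr::map_dfr(params, function(par) {
      pull_values <- function(grp) {
        samples <- sub[sub$group == grp, ]
        if (unit == "event") {
          unlist(purrr::map(samples$microglia, ~ .x[[par]]), use.names = FALSE)
        } else {
          purrr::map_dbl(samples$microglia, function(ev) {
            if (nrow(ev) == 0) NA_real_ else compute_mfi(ev[[par]], statistic)
          })
        }
      }
      x <- pull_values("CCI")
      y <- pull_values("sham")
      x <- x[is.finite(x)]; y <- y[is.finite(y)]
      if (length(x) == 0 || length(y) == 0) {
        return(tibble::tibble(
          panel = panel, hemisphere = hemisphere, parameter = par,
          U = NA_real_, p_value = NA_real_,
          mfi_cci = NA_real_, mfi_sham = NA_real_,
          n_cci = length(x), n_sham = length(y),
          note = "no gated events in one condition"))
      }
      mw <- mann_whitney_u(x, y)
      tibble::tibble(
        panel = panel, hemisphere = hemisphere, parameter = par,
        U = mw$U, p_value = max(mw$p_value, 1e-300),
        mfi_cci = compute_mfi(x, statistic),
        mfi_sham = compute_mfi(y, statistic),
        n_cci = length(x), n_sham = length(y), note = NA_character_)
    })
    fdr <- bh_fdr(rows$p_value, q)
    rows$p_adjusted <- fdr$p_adjusted
    rows$fdr_significant <- fdr$rejected
    rows
  })
  res |>
    dplyr::mutate(
      direction = dplyr::case_when(
        !.data$fdr_significant | is.na(.data$fdr_significant) ~ "none",
        .data$mfi_cci > .data$mfi_sham ~ "up",
        .data$mfi_cci < .data$mfi_sham ~ "down",
        TRUE ~ "none"),
      comparison = paste0("CCI-", substr(.data$hemisphere, 1, 5),
                          " vs sham-", substr(.data$hemisphere, 1, 5)),
      scale = scale_note, mfi_statistic = statistic, unit = unit) |>
    structure(class = c("cg_screen", "tbl_df", "tbl", "data.frame"))
}

#' Quantile-quantile comparison of two distributions
#'
#' Quantiles of both samples on the probe grid `i / (n_probes + 1)` with
#' linear interpolation between order statistics. When the distributions
#' coincide the curve lies on `y = x`; the location summaries quantify the
#' departure: median vertical displacement from the identity line and the
#' signed area between the curve and the identity (trapezoidal rule over the
#' probe grid, negative when `y` is stochastically smaller).
#'
#' @param x Reference sample (e.g. sham), horizontal axis.
#' @param y Comparison sample (e.g. injured), vertical axis.
#' @param n_probes Number of probe quantiles (>= 3).
#' @return A `cg_qq` list: `curve` tibble (`probe`, `q_x`, `q_y`),
#'   `median_shift`, `signed_area`.
#' @export
qq_curve <- function(x, y, n_probes = 99) {
  if (length(x) == 0 || length(y) == 0) abort("both samples must be non-empty")
  if (n_probes < 3) abort("`n_probes` must be at least 3")
  probes <- seq_len(n_probes) / (n_probes + 1)
  qx <- unname(quantile(x, probes, type = 7))
  qy <- unname(quantile(y, probes, type = 7))
  diff <- qy - qx
  area <- sum((diff[-1] + diff[-length(diff)]) / 2 * base::diff(qx))
  structure(list(
    curve = tibble::tibble(probe = probes, q_x = qx, q_y = qy),
    median_shift = median(diff), signed_area = area), class = "cg_qq")
}

#' QQ distribution-shift summaries across a gated cohort
#'
#' One QQ comparison per (panel, hemisphere, parameter), injured against the
#' corresponding sham, on pooled microglia events.
#'
#' @inheritParams marker_screen
#' @param n_probes Probe grid size for [qq_curve()].
#' @return Tibble with list column `qq` plus `median_shift`, `signed_area`.
#' @export
cohort_qq <- function(cohort, parameters = NULL, n_probes = 99) {
  families <- tidyr::expand_grid(panel = unique(cohort$panel),
                                 hemisphere = unique(cohort$hemisphere))
  purrr::pmap_dfr(families, function(panel, hemisphere) {
    params <- parameters %||% c("FSC_A", "SSC_A", panel_markers(panel))
    sub <- cohort[cohort$panel == panel & cohort$hemisphere == hemisphere, ]
    purrr::map_dfr(params, function(par) {
      y <- unlist(purrr::map(sub$microglia[sub$group == "CCI"], ~ .x[[par]]))
      x <- unlist(purrr::map(sub$microglia[sub$group == "sham"], ~ .x[[par]]))
      if (length(x) == 0 || length(y) == 0) {
        return(tibble::tibble(panel = panel, hemisphere = hemisphere,
                              parameter = par, qq = list(NULL),
                              median_shift = NA_real_,
                              signed_area = NA_real_))
      }
      curve <- qq_curve(x, y, n_probes)
      tibble::tibble(panel = panel, hemisphere = hemisphere, parameter = par,
                     qq = list(curve), median_shift = curve$median_shift,
                     signed_area = curve$signed_area)
    })
  })
}
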