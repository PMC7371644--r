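#' Hierarchical gating strategies
#'
#' A strategy is a rooted tree of named gates; each node's population is the
#' intersection of its parent's population with its own gate mask. The
#' implicit root `"all"` contains every event.
#'
#' @param nodes List of nodes, each a list with `name`, `parent` (node name
#'   or `"all"`) and `gate` (a `cg_gate`).
#' @return A `cg_strategy` object.
#' @export
gating_strategy <- function(nodes) {
  names <- vapply(nodes, `[[`, character(1), "name")
  if (anyDuplicated(names)) abort("gate node names must be unique")
  parents <- vapply(nodes, `[[`, character(1), "parent")
  for (i in seq_along(nodes)) {
    if (parents[i] != "all" && !parents[i] %in% names[seq_len(i - 1)]) {
      abort(sprintf(
        "node '%s': parent '%s' must be defined earlier in the tree",
        names[i], parents[i]))
    }
  }
  structure(list(nodes = nodes), class = "cg_strategy")
}

#' The standard microglia identification strategy
#'
#' Mirrors the conventional hierarchy: main cell population on scatter
#' (excludes debris and beads), singlets by FSC area-vs-height ratio, live
#' cells by viability-dye exclusion (valley threshold), then sequential
#' CD45+, CD11b/c+ and P2y12+ positivity to reach microglia. Counting beads
#' are a sibling node gated on the bead flag channel. Positivity thresholds
#' are on the arcsinh scale and sit between the negative populations
#' (debris, P2y12-negative infiltrate around 0.3) and the positive ones
#' (>= 2.2); override per channel for other staining intensities.
#'
#' @param marker_thresholds Named vector of positivity thresholds for the
#'   three identification markers.
#' @param fsc_min Lower FSC-A bound of the main cell population.
#' @param singlet_band FSC-H/FSC-A ratio band.
#' @param bead_threshold Bead flag channel threshold (arcsinh scale).
#' @param viability_fallback Fallback viability threshold when valley
#'   finding fails.
#' @return A `cg_strategy`.
#' @export
default_gating_strategy <- function(marker_thresholds = c(CD45 = 1.2,
                                                          CD11bc = 1.2,
                                                          P2y12 = 1.2),
                                    fsc_min = 40000,
                                    singlet_band = c(0.75, 1.10),
                                    bead_threshold = 2.0,
                                    viability_fallback = 1.8) {
  gating_strategy(list(
    list(name = "beads", parent = "all",
         gate = gate_threshold("beads", "Bead", bead_threshold, "above")),
    list(name = "cells", parent = "all",
         gate = gate_rectangle("cells", c("FSC_A", "SSC_A"),
                               xlim = c(fsc_min, Inf), ylim = c(-Inf, Inf))),
    list(name = "singlets", parent = "cells",
         gate = gate_ratio_band("singlets", c("FSC_A", "FSC_H"),
                                singlet_band)),
    list(name = "live", parent = "singlets",
         gate = gate_threshold("live", "Viability", direction = "below",
                               policy = "valley",
                               fallback = viability_fallback)),
    list(name = "CD45pos", parent = "live",
         gate = gate_threshold("CD45pos", "CD45",
                               marker_thresholds[["CD45"]], "above")),
    list(name = "CD11bcpos", parent = "CD45pos",
         gate = gate_threshold("CD11bcpos", "CD11bc",
                               marker_thresholds[["CD11bc"]], "above")),
    list(name = "microglia", parent = "CD11bcpos",
         gate = gate_threshold("microglia", "P2y12",
                               marker_thresholds[["P2y12"]], "above"))
  ))
}

#' Execute a gating strategy on one event table
#'
#' @param events Transformed event tibble.
#' @param strategy A `cg_strategy`.
#' @return A `cg_gating` list: `populations` tibble (node, parent, events,
#'   pct_parent, pct_total) and the logical `masks` matrix (events x nodes).
#'   Child masks are subsets of their parents by construction; an empty
#'   table yields all-zero populations.
#' @export
run_strategy <- function(events, strategy) {
  n <- nrow(events)
  node_names <- vapply(strategy$nodes, `[[`, character(1), "name")
  masks <- matrix(FALSE, n, length(node_names),
                  dimnames = list(NULL, node_names))
  for (node in strategy$nodes) {
    parent_mask <- if (node$parent == "all") rep(TRUE, n) else
      masks[, node$parent]
    masks[, node$name] <- apply_gate(events, node$gate, parent_mask)
  }
  parents <- vapply(strategy$nodes, `[[`, character(1), "parent")
  n_node <- colSums(masks)
  n_parent <- vapply(parents, function(p) {
    if (p == "all") n else sum(masks[, p])
  }, numeric(1))
  populations <- tibble::tibble(
    node = node_names, parent = parents,
    events = as.integer(n_node),
    pct_parent = ifelse(n_parent > 0, 100 * n_node / n_parent, 0),
    pct_total = if (n > 0) 100 * n_node / n else 0)
  structure(list(populations = populations, masks = masks,
                 n_total = n), class = "cg_gating")
}

#' @export
print.cg_gating <- function(x, ...) {
  cat("<cg_gating>", x$n_total, "events\n")
  print(x$populations)
  invisible(x)
}

#' Bead-based absolute quantification
#'
#' `cells_per_mg = events * (beads_added / bead_events) / tissue_mass_mg`.
#'
#' @param events Cell events in the population of interest.
#' @param bead_events Bead events acquired alongside.
#' @param beads_added Beads spiked into the tube.
#' @param tissue_mass_mg Tissue mass, mg.
#' @param population Population label carried through.
#' @return One-row tibble (population, events, cells_per_mg).
#' @export
absolute_count <- function(events, bead_events, beads_added, tissue_mass_mg,
                           population = "microglia") {
  if (bead_events <= 0) {
    abort("no bead events acquired: absolute quantification impossible")
  }
  if (tissue_mass_mg <= 0) abort("`tissue_mass_mg` must be positive")
  tibble::tibble(
    population = population, events = as.integer(events),
    cells_per_mg = events * (beads_added / bead_events) / tissue_mass_mg)
}

#' Gate every sample of a cohort
#'
#' Runs the strategy per sample and attaches the gating result, the gated
#' microglia events and the absolute microglia count.
#'
#' @param cohort Transformed `cg_cohort` (see [prepare_cohort()]).
#' @param strategy A `cg_strategy`.
#' @return Cohort tibble with extra list columns `gating`, `microglia`
#'   (event tibbles) and columns `bead_events`, `microglia_events`,
#'   `cells_per_mg`.
#' @export
gate_cohort <- function(cohort, strategy = default_gating_strategy()) {
  res <- purrr::map(cohort$events, run_strategy, strategy = strategy)
  cohort$gating <- res
  cohort$bead_events <- vapply(res, function(r) {
    sum(r$masks[, "beads"])
  }, numeric(1))
  cohort$microglia_events <- vapply(res, function(r) {
    sum(r$masks[, "microglia"])
  }, numeric(1))
  cohort$microglia <- purrr::map2(cohort$events, res, function(ev, r) {
    ev[r$masks[, "microglia"], , drop = FALSE]
  })
  cohort$cells_per_mg <- purrr::pmap_dbl(
    list(cohort$microglia_events, cohort$bead_events, cohort$beads_added,
         cohort$tissue_mass_mg),
    function(ev, be, ba, m) absolute_count(ev, be, ba, m)$cells_per_mg)
  cohort
}

#' Fold change of a condition against the mean of reference conditions
#'
#' @param counts Tibble with columns `group`, `hemisphere`, `cells_per_mg`
#'   (one row per sample; averaged per condition internally).
#' @param target Length-2 character `c(group, hemisphere)` of the condition
#'   of interest.
#' @param reference Tibble of reference conditions (columns `group`,
#'   `hemisphere`); defaults to the other three conditions.
#' @return Fold-change ratio (target mean over mean of reference-condition
#'   means).
#' @export
fold_change_vs_reference <- function(counts,
                                     target = c("CCI", "ipsilateral"),
                                     reference = NULL) {
  per_condition <- counts |>
    dplyr::group_by(.data$group, .data$hemisphere) |>
    dplyr::summarise(cells_per_mg = mean(.data$cells_per_mg), .groups = "drop")
  if (is.null(reference)) {
    reference <- condition_grid() |>
      dplyr::anti_join(tibble::tibble(group = target[1],
                                      hemisphere = target[2]),
                       by = c("group", "hemisphere"))
  }
  if (nrow(reference) == 0) abort("reference condition set is empty")
  tgt <- per_condition |>
    dplyr::filter(.data$group == target[1], .data$hemisphere == target[2])
  ref <- per_condition |>
    dplyr::semi_join(reference, by = c("group", "hemisphere"))
  if (nrow(tgt) != 1 || nrow(ref) == 0) {
    abort("target or reference conditions missing from `counts`")
  }
  ref_mean <- mean(ref$cells_per_mg)
  if (ref_mean == 0) abort("reference mean is zero; fold change undefined")
  tgt$cells_per_mg / ref_mean
}

#' Compare recovered populations against the ground-truth manifest
#'
#' Each event is assigned a predicted label from the gating masks (bead,
#' debris, doublet, dead, microglia, infiltrate, in hierarchy order) and
#' precision/recall/F1 are computed per true population.
#'
#' @param gating A `cg_gating` from [run_strategy()].
#' @param manifest The sample's `cg_manifest`.
#' @return Tibble with population, n_true, n_pred, precision, recall, f1.
#' @export
population_f1 <- function(gating, manifest) {
  m <- gating$masks
  pred <- rep("infiltrate", nrow(m))
  pred[!m[, "cells"]] <- "debris"
  pred[m[, "cells"] & !m[, "singlets"]] <- "doublet"
  pred[m[, "singlets"] & !m[, "live"]] <- "dead"
  pred[m[, "microglia"]] <- "microglia"
  pred[m[, "beads"]] <- "bead"
  truth <- manifest$labels
  purrr::map_dfr(sort(unique(truth)), function(pop) {
    tp <- sum(pred == pop & truth == pop)
    fp <- sum(pred == pop & truth != pop)
    fn <- sum(pred != pop & truth == pop)
    precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    f1 <- if (isTRUE(precision + recall > 0)) {
      2 * precision * recall / (precision + recall)
    } else NA_real_
    tibble::tibble(population = pop, n_true = tp + fn,
                   n_pred = tp + fp, precision = precision,
                   recall = recall, f1 = f1)
  })
}
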