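#' Default end-to-end run configuration
#'
#' A nested list understood by [validate_config()] and [run_pipeline()];
#' serialise it with `yaml::write_yaml()` or `jsonlite::write_json()` to
#' keep runs reproducible. All statistical settings carry their conventional
#' defaults: marker screen FDR 0.05, differential-correlation FDR 0.01,
#' tenfold cross-validation averaged over 10 runs, tSNE perplexity 30.
#'
#' @param seed Master seed recorded in every output.
#' @return Config list.
#' @export
default_config <- function(seed = 1L) {
  list(
    input = list(mode = "synthetic",
                 design = list(n_animals = 3, n_events = 10000,
                               tissue_mass_mg = 20, beads_added = 5000),
                 animal_sigma = 0.05, files = NULL),
    panels = list(M1 = panel_markers("M1"), M2 = panel_markers("M2")),
    compensation = NULL,
    transform = list(cofactor = 150),
    gating = list(marker_thresholds = c(CD45 = 1.2, CD11bc = 1.2,
                                        P2y12 = 1.2),
                  fsc_min = 40000, singlet_band = c(0.75, 1.10),
                  bead_threshold = 2.0, viability_fallback = 1.8),
    stats = list(mfi_statistic = "median", fdr_markers = 0.05,
                 fdr_correlation = 0.01, qq_probes = 99),
    classify = list(classifiers = c("logistic", "random_forest", "rbf_svm"),
                    k = 10, runs = 10, n_per_class = 1500,
                    hemispheres = c("ipsilateral", "contralateral")),
    embedding = list(enabled = TRUE, panel = "M1", n_per_sample = 500,
                     perplexity = 30, n_iter = 500),
    seed = as.integer(seed))
}

#' Validate and complete a run configuration
#'
#' Fills defaults, resolves cross-references and aggregates all problems
#' into one readable error.
#'
#' @param config Config list (possibly partial), or a path to a YAML/JSON
#'   file.
#' @return The completed config, invisibly errors otherwise.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  full <- utils::modifyList(default_config(), config)
  full$seed <- as.integer(full$seed)
  errors <- character()
  note <- function(msg) errors <<- c(errors, msg)

  if (!full$input$mode %in% c("synthetic", "files")) {
    note(sprintf("input mode '%s' unknown (synthetic|files)", full$input$mode))
  }
  if (full$input$mode == "files" && is.null(full$input$files)) {
    note("input mode 'files' needs an `input$files` sample table")
  }
  for (p in names(full$panels)) {
    missing <- setdiff(identification_markers(), full$panels[[p]])
    if (length(missing)) {
      note(sprintf("panel %s lacks identification marker(s): %s",
                   p, paste(missing, collapse = ", ")))
    }
  }
  for (fdr in c(full$stats$fdr_markers, full$stats$fdr_correlation)) {
    if (!is.numeric(fdr) || fdr <= 0 || fdr >= 1) {
      note(sprintf("FDR level %s outside (0, 1)", format(fdr)))
    }
  }
  if (full$transform$cofactor <= 0) note("transform cofactor must be positive")
  thr <- full$gating$marker_thresholds
  known <- unique(unlist(full$panels))
  for (ch in names(thr)) {
    if (!ch %in% known) {
      note(sprintf("gating threshold references unknown marker '%s'", ch))
    }
  }
  bad_cl <- setdiff(full$classify$classifiers,
                    c("logistic", "random_forest", "rbf_svm"))
  if (length(bad_cl)) {
    note(sprintf("unknown classifier(s): %s", paste(bad_cl, collapse = ", ")))
  }
  if (length(errors)) {
    abort(paste0("invalid configuration:\n",
                 paste0("  - ", errors, collapse = "\n")))
  }
  full
}

#' Run the full analysis pipeline
#'
#' Generate or ingest -> compensate/transform -> gate -> quantify -> marker
#' screen -> QQ -> differential correlation -> discriminate -> embed, under
#' one config and one master seed. Reruns with an identical config are
#' identical.
#'
#' @param config Config list or path (see [default_config()]).
#' @param out_dir Optional directory; when given, all result tables are
#'   written there as CSV/JSON via [write_report()].
#' @return A `cg_report` list: `counts`, `fold_change`, `screen`, `qq`,
#'   `correlation`, `classifiers`, `embedding`, `cohort`, and a `provenance`
#'   block (config, seed, config hash, package version).
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  config <- validate_config(config)
  seed <- config$seed
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }

  cohort <- stage("input", {
    if (config$input$mode == "synthetic") {
      d <- config$input$design
      simulate_cohort(
        cohort_design(n_animals = d$n_animals, n_events = d$n_events,
                      tissue_mass_mg = d$tissue_mass_mg,
                      beads_added = d$beads_added),
        seed = seed, animal_sigma = config$input$animal_sigma,
        cofactor = config$transform$cofactor)
    } else {
      read_cohort_files(config$input$files)
    }
  })

  spill <- if (!is.null(config$compensation)) {
    if (is.character(config$compensation)) read_spillover(config$compensation)
    else config$compensation
  }
  cohort <- stage("prepare", prepare_cohort(cohort, spill = spill,
                                            cofactor = config$transform$cofactor))
  strategy <- default_gating_strategy(
    marker_thresholds = config$gating$marker_thresholds,
    fsc_min = config$gating$fsc_min,
    singlet_band = config$gating$singlet_band,
    bead_threshold = config$gating$bead_threshold,
    viability_fallback = config$gating$viability_fallback)
  cohort <- stage("gating", gate_cohort(cohort, strategy))

  counts <- cohort |>
    dplyr::select("sample_id", "animal_id", "group", "hemisphere", "panel",
                  "microglia_events", "bead_events", "cells_per_mg")
  fold_change <- stage("quantification", fold_change_vs_reference(counts))

  screen <- stage("marker_screen",
                  marker_screen(cohort, q = config$stats$fdr_markers,
                                statistic = config$stats$mfi_statistic))
  qq <- stage("qq", cohort_qq(cohort, n_probes = config$stats$qq_probes))
  correlation <- stage("correlation",
                       cohort_correlation(cohort,
                                          q = config$stats$fdr_correlation,
                                          seed = seed))
  cls <- config$classify
  classifiers <- stage("discrimination", purrr::map_dfr(
    cls$hemispheres, function(h) {
      cohort_discriminate(cohort, hemisphere = h,
                          classifiers = cls$classifiers,
                          n_per_class = cls$n_per_class, k = cls$k,
                          runs = cls$runs, seed = seed)
    }))
  embedding <- if (isTRUE(config$embedding$enabled)) {
    e <- config$embedding
    stage("embedding",
          cohort_embedding(cohort, panel = e$panel,
                           n_per_sample = e$n_per_sample,
                           perplexity = e$perplexity, n_iter = e$n_iter,
                           seed = seed))
  }

  report <- structure(list(
    counts = counts, fold_change = fold_change, screen = screen, qq = qq,
    correlation = correlation, classifiers = classifiers,
    embedding = embedding, cohort = cohort,
    provenance = list(
      seed = seed, config = config, config_hash = rlang::hash(config),
      package_version = as.character(utils::packageVersion("cytoglia")))),
    class = "cg_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.cg_report <- function(x, ...) {
  cat("<cg_report> seed", x$provenance$seed,
      "config", x$provenance$config_hash, "\n")
  cat(sprintf("  microglia fold change (CCI ipsi vs others): %.2f\n",
              x$fold_change))
  cat(sprintf("  markers FDR-flagged: %d of %d\n",
              sum(x$screen$fdr_significant, na.rm = TRUE), nrow(x$screen)))
  cat(sprintf("  significantly higher correlation fractions: %s\n",
              paste(sprintf("%s/%s %.0f%%", x$correlation$panel,
                            substr(x$correlation$hemisphere, 1, 5),
                            100 * x$correlation$fraction_significantly_higher),
                    collapse = ", ")))
  if (nrow(x$classifiers)) {
    best <- x$classifiers[which.max(x$classifiers$auc_mean), ]
    cat(sprintf("  best classifier: %s %s/%s AUC %.3f +- %.4f\n",
                best$classifier, best$panel, best$hemisphere,
                best$auc_mean, best$auc_sd))
  }
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' CSV tables for counts, marker screen, QQ summaries, per-pair correlation
#' results and classifier AUCs; Cohen's-q matrices as CSV matrices;
#' embedding coordinates as CSV; provenance as JSON.
#'
#' @param report `cg_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    write.csv(df, file.path(dir, name), row.names = FALSE)
  }
  w(report$counts, "population_counts.csv")
  w(dplyr::select(report$screen, -dplyr::any_of("qq")), "marker_screen.csv")
  w(dplyr::select(report$qq, -"qq"), "qq_summaries.csv")
  purrr::pwalk(report$correlation, function(panel, hemisphere, screen, ...) {
    w(screen$pairs, sprintf("correlation_pairs_%s_%s.csv", panel, hemisphere))
    write.csv(screen$q_matrix,
              file.path(dir, sprintf("cohens_q_%s_%s.csv", panel, hemisphere)))
  })
  w(dplyr::select(report$classifiers, -"result"), "classifier_aucs.csv")
  if (!is.null(report$embedding)) {
    w(dplyr::bind_cols(report$embedding$coords,
                       report$embedding$events[c("sample_id", "group",
                                                 "hemisphere")]),
      "embedding_coords.csv")
  }
  jsonlite::write_json(
    list(seed = report$provenance$seed,
         config_hash = report$provenance$config_hash,
         package_version = report$provenance$package_version,
         fold_change = report$fold_change),
    file.path(dir, "provenance.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Assemble a cohort from existing event files
#'
#' @param files Data frame with columns `path`, `animal_id`, `group`,
#'   `hemisphere`, `panel`, `tissue_mass_mg`, `beads_added`.
#' @return A `cg_cohort` tibble (manifests are `NULL`: no ground truth for
#'   real data).
#' @export
read_cohort_files <- function(files) {
  files <- tibble::as_tibble(files)
  need <- c("path", "animal_id", "group", "hemisphere", "panel",
            "tissue_mass_mg", "beads_added")
  missing <- setdiff(need, names(files))
  if (length(missing)) {
    abort(sprintf("file manifest lacks column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  out <- files |>
    dplyr::mutate(
      sample_id = paste(.data$animal_id, .data$group,
                        substr(.data$hemisphere, 1, 5), .data$panel,
                        sep = "_"),
      seed = NA_integer_,
      events = purrr::map(.data$path, ~ read_events(.x)$events),
      manifest = list(NULL)) |>
    dplyr::select(-"path")
  class(out) <- c("cg_cohort", class(out))
  out
}
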