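#' Describe one event population for the synthetic generator
#'
#' The generator draws each population from a multivariate normal on the
#' generation scale: linear for scatter channels, arcsinh-transformed for
#' fluorescence channels. Marker correlation is injected through a Gaussian
#' copula for the microglia population (see [effect_model()]); all other
#' populations use independent channels. `FSC_H` is never listed in
#' `locations`: for singlets it is derived as `FSC_A` times a pulse-shape
#' ratio close to 1, and doublets are built as pairwise sums of singlet
#' events so `FSC_A` doubles while `FSC_H` does not.
#'
#' @param name One of `"debris"`, `"doublet"`, `"dead"`, `"microglia"`,
#'   `"infiltrate"`, `"bead"`.
#' @param base_fraction Expected fraction of cell events (beads are spiked
#'   separately and must use `base_fraction = 0`).
#' @param locations Named numeric vector, channel -> location on the
#'   generation scale. Empty for `doublet` (derived population).
#' @param scales Named numeric vector of positive spreads, same names as
#'   `locations`.
#' @param is_viable,is_singlet Flags describing where the population sits in
#'   the gating hierarchy.
#' @return A `cg_population` list.
#' @export
population_spec <- function(name, base_fraction, locations = numeric(),
                            scales = numeric(), is_viable = TRUE,
                            is_singlet = TRUE) {
  stopifnot(is.character(name), length(name) == 1)
  if (!is.numeric(base_fraction) || base_fraction < 0 || base_fraction > 1) {
    abort("`base_fraction` must lie in [0, 1]")
  }
  if (length(scales) && any(scales <= 0)) {
    abort(sprintf("all channel scales must be positive (population '%s')", name))
  }
  if (!setequal(names(locations), names(scales))) {
    abort("`locations` and `scales` must name the same channels")
  }
  structure(
    list(name = name, base_fraction = base_fraction,
         locations = locations, scales = scales[names(locations)],
         is_viable = isTRUE(is_viable), is_singlet = isTRUE(is_singlet)),
    class = "cg_population")
}

#' Default population mixture emulating a CD11b/c-enriched brain digest
#'
#' Six populations: debris, doublets (aggregates), dead cells, microglia,
#' infiltrating myeloid cells and counting beads. Locations are on the
#' generation scale (linear for scatter, arcsinh with cofactor 150 for
#' fluorescence). The identification markers (CD45, CD11b/c, P2y12) are
#' tight (spread 0.30) and separate microglia from infiltrating cells by
#' several standard deviations, as on a well-compensated instrument; the
#' activation markers are broad (spread 0.75), which is what makes the
#' downstream discrimination problem non-trivial.
#'
#' @param panel `"M1"` or `"M2"`.
#' @param microglia_fraction Baseline (sham) microglia fraction of cell
#'   events.
#' @return List of [population_spec()] objects.
#' @export
default_populations <- function(panel = c("M1", "M2"),
                                microglia_fraction = 0.04) {
  panel <- match.arg(panel)
  markers <- panel_markers(panel)

  marker_loc <- function(pop) {
    full <- switch(pop,
      debris     = c(CD45 = 0.3, CD11bc = 0.3, P2y12 = 0.3, CD32 = 0.3,
                     CD86 = 0.3, CD200R = 0.3, RT1B = 0.3, CD163 = 0.3),
      microglia  = ,
      dead       = c(CD45 = 2.4, CD11bc = 2.6, P2y12 = 2.2, CD32 = 1.6,
                     CD86 = 1.8, CD200R = 1.7, RT1B = 1.9, CD163 = 1.5),
      infiltrate = c(CD45 = 3.4, CD11bc = 2.8, P2y12 = 0.15, CD32 = 1.8,
                     CD86 = 2.1, CD200R = 0.8, RT1B = 2.2, CD163 = 1.7),
      bead       = c(CD45 = 1.0, CD11bc = 1.0, P2y12 = 1.0, CD32 = 1.0,
                     CD86 = 1.0, CD200R = 1.0, RT1B = 1.0, CD163 = 1.0))
    full[markers]
  }
  marker_scale <- function(pop) {
    s <- switch(pop,
      debris = rep(0.30, length(markers)),
      bead = rep(0.20, length(markers)),
      ifelse(markers %in% identification_markers(), 0.30, 0.75))
    # P2y12 is genuinely absent on infiltrating myeloid cells: tight negative
    if (pop == "infiltrate") s[markers == "P2y12"] <- 0.25
    setNames(s, markers)
  }
  base <- function(pop, fsc, fsc_s, ssc, ssc_s, via, via_s, bead, bead_s) {
    c(FSC_A = fsc, SSC_A = ssc, Viability = via, Bead = bead,
      marker_loc(pop)) ->
      loc
    sc <- c(FSC_A = fsc_s, SSC_A = ssc_s, Viability = via_s, Bead = bead_s,
            marker_scale(pop))
    list(loc = loc, sc = sc[names(loc)])
  }

  debris <- base("debris", 15000, 5000, 8000, 3000, 0.5, 0.30, 0.2, 0.20)
  dead <- base("dead", 90000, 18000, 50000, 13000, 3.2, 0.30, 0.2, 0.20)
  mg <- base("microglia", 100000, 15000, 45000, 10000, 0.4, 0.30, 0.2, 0.20)
  inf <- base("infiltrate", 95000, 15000, 55000, 12000, 0.4, 0.30, 0.2, 0.20)
  bead <- base("bead", 12000, 1500, 70000, 5000, 0.2, 0.15, 4.0, 0.15)

  # non-microglia populations share the remaining mass in fixed proportions
  # (0.30 : 0.10 : 0.12 : 0.44 at the default microglia fraction of 0.04)
  w <- c(debris = 0.30, doublet = 0.10, dead = 0.12, infiltrate = 0.44) / 0.96
  w <- w * (1 - microglia_fraction)
  list(
    population_spec("debris", w[["debris"]], debris$loc, debris$sc),
    population_spec("doublet", w[["doublet"]], is_singlet = FALSE),
    population_spec("dead", w[["dead"]], dead$loc, dead$sc,
                    is_viable = FALSE),
    population_spec("microglia", microglia_fraction, mg$loc, mg$sc),
    population_spec("infiltrate", w[["infiltrate"]], inf$loc, inf$sc),
    population_spec("bead", 0, bead$loc, bead$sc)
  )
}

#' Condition-specific effect applied to the microglia population
#'
#' Injury effects are modelled as (i) a multiplier on the microglia fraction
#' of cell events, (ii) additive location shifts on the generation scale per
#' channel, and (iii) a marker correlation matrix injected via Gaussian
#' copula into the microglia population. Sham conditions must carry zero
#' shifts and multiplier 1 (their correlation matrix is the baseline
#' structure).
#'
#' @param group `"sham"` or `"CCI"`.
#' @param hemisphere `"ipsilateral"` or `"contralateral"`.
#' @param microglia_fraction_multiplier Positive scalar.
#' @param channel_shifts Named numeric vector of signed location shifts.
#' @param correlation_matrix Symmetric PSD matrix with unit diagonal over the
#'   panel markers (dimnames required).
#' @return A `cg_effect` list.
#' @export
effect_model <- function(group, hemisphere,
                         microglia_fraction_multiplier = 1,
                         channel_shifts = numeric(),
                         correlation_matrix = NULL) {
  group <- match.arg(group, c("sham", "CCI"))
  hemisphere <- match.arg(hemisphere, c("ipsilateral", "contralateral"))
  if (microglia_fraction_multiplier <= 0) {
    abort("`microglia_fraction_multiplier` must be positive")
  }
  if (group == "sham") {
    if (microglia_fraction_multiplier != 1 ||
        (length(channel_shifts) && any(channel_shifts != 0))) {
      abort("sham conditions must have multiplier 1 and all shifts 0")
    }
  }
  if (!is.null(correlation_matrix)) {
    check_correlation_matrix(correlation_matrix)
    if (is.null(dimnames(correlation_matrix)[[1]])) {
      abort("`correlation_matrix` needs marker dimnames")
    }
  }
  structure(
    list(group = group, hemisphere = hemisphere,
         microglia_fraction_multiplier = microglia_fraction_multiplier,
         channel_shifts = channel_shifts,
         correlation_matrix = correlation_matrix),
    class = "cg_effect")
}

#' Build a marker correlation matrix with a boosted block
#'
#' @param markers Marker names.
#' @param base Baseline pairwise correlation.
#' @param boost_markers Markers whose mutual correlations are raised.
#' @param boost Correlation within the boosted set.
#' @param pairs Optional list of length-2 character vectors for individual
#'   pair boosts (applied after `boost_markers`).
#' @return Correlation matrix with dimnames.
#' @export
marker_correlation <- function(markers, base = 0.10, boost_markers = NULL,
                               boost = 0.45, pairs = NULL) {
  m <- length(markers)
  R <- matrix(base, m, m, dimnames = list(markers, markers))
  diag(R) <- 1
  if (!is.null(boost_markers)) {
    idx <- markers %in% boost_markers
    R[idx, idx] <- boost
    diag(R) <- 1
  }
  for (p in pairs) {
    R[p[1], p[2]] <- R[p[2], p[1]] <- boost
  }
  check_correlation_matrix(R)
  R
}

#' Default condition effects
#'
#' Sham conditions are null. The injured (CCI) ipsilateral hemisphere gets
#' the full activation signature: microglia fraction multiplied by 16,
#' larger and more granular cells (FSC/SSC up), CD45 and CD11b/c up, P2y12
#' down, CD32 and CD163 up, CD86 and RT1B down, CD200R unchanged, and a
#' boosted marker correlation block. The contralateral CCI hemisphere gets
#' the same directions at much smaller magnitude for the markers that remain
#' detectable there, no fraction change, and a single boosted correlation
#' pair (CD11b/c-CD163 in the M2 panel). Magnitudes were calibrated once so
#' a ridge-logistic classifier on pooled microglia events lands in the
#' 0.75-0.90 AUC band for ipsilateral injury vs sham; see the methods
#' vignette.
#'
#' @param panel `"M1"` or `"M2"`.
#' @return Tibble with columns `group`, `hemisphere`, `panel` and a list
#'   column `effect` of [effect_model()] objects.
#' @export
default_effects <- function(panel = c("M1", "M2")) {
  panel <- match.arg(panel)
  markers <- panel_markers(panel)
  base_R <- marker_correlation(markers)

  shift_full <- c(FSC_A = 25000, SSC_A = 15000,
                  CD45 = 0.17, CD11bc = 0.13, P2y12 = -0.17,
                  CD32 = 0.38, CD86 = -0.27,
                  CD200R = 0, RT1B = -0.27, CD163 = 0.34)
  shift_contra <- c(FSC_A = 5000, SSC_A = 3000,
                    CD45 = 0.05, CD11bc = 0.04, P2y12 = -0.05,
                    CD32 = 0, CD86 = -0.08,
                    CD200R = 0, RT1B = -0.08, CD163 = 0)
  keep <- c("FSC_A", "SSC_A", markers)

  ipsi_R <- if (panel == "M1") {
    marker_correlation(markers, boost_markers = c("CD45", "CD11bc", "CD32", "CD86"))
  } else {
    marker_correlation(markers,
                       boost_markers = c("CD45", "CD11bc", "CD200R", "CD163", "RT1B"))
  }
  contra_R <- if (panel == "M2") {
    marker_correlation(markers, pairs = list(c("CD11bc", "CD163")), boost = 0.55)
  } else {
    base_R
  }

  tibble::tibble(
    group = c("sham", "sham", "CCI", "CCI"),
    hemisphere = rep(c("ipsilateral", "contralateral"), 2),
    panel = panel,
    effect = list(
      effect_model("sham", "ipsilateral", correlation_matrix = base_R),
      effect_model("sham", "contralateral", correlation_matrix = base_R),
      effect_model("CCI", "ipsilateral", 16, shift_full[keep], ipsi_R),
      effect_model("CCI", "contralateral", 1, shift_contra[keep], contra_R)
    )
  )
}

#' @rdname default_effects
#' @details `null_effects()` returns the same grid with every condition null
#'   (all shifts 0, multiplier 1, baseline correlation): the zero-effect
#'   cohort used for type-I calibration.
#' @export
null_effects <- function(panel = c("M1", "M2")) {
  panel <- match.arg(panel)
  base_R <- marker_correlation(panel_markers(panel))
  grid <- condition_grid()
  grid$panel <- panel
  grid$effect <- purrr::map2(grid$group, grid$hemisphere, function(g, h) {
    e <- effect_model("sham", h, correlation_matrix = base_R)
    e$group <- g # label only; all effects are null
    e
  })
  grid
}

generation_channels <- function(populations) {
  names(populations[[which(vapply(populations, function(p)
    length(p$locations) > 0, logical(1)))[1]]]$locations)
}

# Draw one population's events on the generation scale.
draw_population <- function(pop, n, channels, markers, shifts = numeric(),
                            R = NULL, offsets = NULL) {
  mu <- pop$locations[channels]
  sc <- pop$scales[channels]
  if (length(shifts)) {
    add <- shifts[intersect(names(shifts), channels)]
    mu[names(add)] <- mu[names(add)] + add
  }
  if (!is.null(offsets)) {
    mult <- offsets$mult[intersect(names(offsets$mult), channels)]
    mu[names(mult)] <- mu[names(mult)] * mult
    add <- offsets$add[intersect(names(offsets$add), channels)]
    mu[names(add)] <- mu[names(add)] + add
  }
  d <- length(channels)
  Rfull <- diag(d)
  dimnames(Rfull) <- list(channels, channels)
  if (!is.null(R)) {
    mk <- intersect(markers, rownames(R))
    Rfull[mk, mk] <- R[mk, mk]
  }
  X <- rmvn_correlated(n, mu, sc, Rfull)
  colnames(X) <- channels
  X
}

# Map generation-scale draws to raw intensities and add FSC_H.
to_raw <- function(X, cofactor, fsc_h_ratio = NULL) {
  channels <- colnames(X)
  cls <- channel_class(channels)
  raw <- X
  fl <- channels[cls != "scatter"]
  raw[, fl] <- asinh_inverse(X[, fl, drop = FALSE], cofactor)
  sc <- channels[cls == "scatter"]
  raw[, sc] <- pmax(raw[, sc, drop = FALSE], 0)
  if (is.null(fsc_h_ratio)) {
    fsc_h_ratio <- rnorm(nrow(X), mean = 0.95, sd = 0.03)
  }
  cbind(raw, FSC_H = raw[, "FSC_A"] * fsc_h_ratio)
}

#' Generate one synthetic cytometry sample with ground truth
#'
#' Events are drawn per population from a multivariate normal on the
#' generation scale (Gaussian copula correlation for microglia markers),
#' mapped back to raw intensities (`sinh(x) * cofactor` for fluorescence),
#' doublets are formed as pairwise sums of viable singlet events (so `FSC_A`
#' doubles but `FSC_H` does not), and counting beads are appended according
#' to the recovery model. Identical inputs and seed give bit-identical
#' output.
#'
#' @param panel `"M1"` or `"M2"`.
#' @param populations List of [population_spec()]; fractions of cell
#'   populations must sum to 1.
#' @param effect [effect_model()] for this sample's condition.
#' @param n_events Number of cell events (>= 100); beads are extra.
#' @param tissue_mass_mg Dissociated tissue mass, mg.
#' @param beads_added Counting beads spiked into the tube.
#' @param bead_recovery Fraction of spiked beads that appear in the event
#'   stream (default 1: all recovered).
#' @param seed Integer seed; required for reproducibility.
#' @param cofactor Arcsinh cofactor linking generation and raw scales.
#' @param animal_offsets Optional list with named vectors `add` (additive,
#'   fluorescence channels) and `mult` (multiplicative, scatter channels)
#'   giving this animal's random intercepts.
#' @return List with `events` (raw-scale tibble, one row per event),
#'   `manifest` (a `cg_manifest`: per-event population labels, realized
#'   counts, the effect and seed used).
#' @export
simulate_sample <- function(panel = c("M1", "M2"),
                            populations = default_populations(panel),
                            effect = effect_model("sham", "ipsilateral"),
                            n_events = 10000, tissue_mass_mg = 20,
                            beads_added = 5000, bead_recovery = 1,
                            seed = 1L, cofactor = 150,
                            animal_offsets = NULL) {
  panel <- match.arg(panel)
  if (n_events < 100) abort("`n_events` must be at least 100")
  if (tissue_mass_mg <= 0) abort("`tissue_mass_mg` must be positive")
  names(populations) <- vapply(populations, `[[`, character(1), "name")
  markers <- panel_markers(panel)

  cell_pops <- setdiff(names(populations), "bead")
  fr <- vapply(populations[cell_pops], `[[`, numeric(1), "base_fraction")
  if (abs(sum(fr) - 1) > 1e-9) {
    abort(sprintf("cell population fractions must sum to 1 (got %.6f)", sum(fr)))
  }
  if (!is.null(populations$bead) && populations$bead$base_fraction != 0) {
    abort("bead population must have base_fraction 0; beads come from `beads_added`")
  }
  if (!is.null(effect$correlation_matrix) &&
      !all(markers %in% rownames(effect$correlation_matrix))) {
    abort("effect correlation matrix must cover all panel markers")
  }

  # injury multiplies the microglia fraction; the rest shrink proportionally
  mult <- effect$microglia_fraction_multiplier
  fr_adj <- fr
  fm <- fr[["microglia"]] * mult
  if (fm >= 1) abort("microglia fraction multiplier pushes the fraction past 1")
  fr_adj[["microglia"]] <- fm
  rest <- setdiff(cell_pops, "microglia")
  fr_adj[rest] <- fr[rest] * (1 - fm) / (1 - fr[["microglia"]])

  withr::with_seed(as.integer(seed), {
    counts <- as.vector(stats::rmultinom(1, n_events, fr_adj))
    names(counts) <- cell_pops
    channels <- generation_channels(populations)

    blocks <- list()
    for (pop in setdiff(cell_pops, "doublet")) {
      n <- counts[[pop]]
      if (n == 0) next
      is_mg <- pop == "microglia"
      X <- draw_population(
        populations[[pop]], n, channels, markers,
        shifts = if (is_mg) effect$channel_shifts else numeric(),
        R = if (is_mg) effect$correlation_matrix else NULL,
        offsets = animal_offsets)
      blocks[[pop]] <- to_raw(X, cofactor)
    }

    # doublets: sums of two viable singlet cell events (raw scale)
    nd <- counts[["doublet"]]
    if (nd > 0) {
      pool_pops <- c("microglia", "infiltrate")
      pw <- fr_adj[pool_pops] / sum(fr_adj[pool_pops])
      comp <- function() {
        lab <- sample(pool_pops, nd, replace = TRUE, prob = pw)
        out <- matrix(NA_real_, nd, length(channels) + 1,
                      dimnames = list(NULL, c(channels, "FSC_H")))
        for (pop in pool_pops) {
          k <- sum(lab == pop)
          if (k == 0) next
          is_mg <- pop == "microglia"
          X <- draw_population(
            populations[[pop]], k, channels, markers,
            shifts = if (is_mg) effect$channel_shifts else numeric(),
            R = if (is_mg) effect$correlation_matrix else NULL,
            offsets = animal_offsets)
          out[lab == pop, ] <- to_raw(X, cofactor)
        }
        out
      }
      a <- comp(); b <- comp()
      dbl <- a + b
      dbl[, "FSC_H"] <- pmax(a[, "FSC_H"], b[, "FSC_H"])
      blocks[["doublet"]] <- dbl
    }

    n_beads <- as.integer(round(beads_added * bead_recovery))
    if (n_beads > 0) {
      X <- draw_population(populations[["bead"]], n_beads, channels, markers)
      blocks[["bead"]] <- to_raw(X, cofactor)
    }

    labels <- rep(names(blocks), vapply(blocks, nrow, integer(1)))
    values <- do.call(rbind, blocks)
    ord <- sample.int(nrow(values)) # shuffle acquisition order
    values <- values[ord, , drop = FALSE]
    labels <- labels[ord]
  })

  col_order <- c("FSC_A", "FSC_H", "SSC_A", "Viability", "Bead", markers)
  events <- tibble::as_tibble(values[, col_order, drop = FALSE])
  events <- set_transform_state(events, "raw")

  manifest <- structure(
    list(labels = labels,
         counts = tibble::tibble(
           population = names(table(labels)),
           n = as.integer(table(labels))),
         effect = effect, seed = as.integer(seed),
         n_events = n_events, beads_added = beads_added,
         bead_recovery = bead_recovery, cofactor = cofactor),
    class = "cg_manifest")
  stopifnot(length(manifest$labels) == nrow(events),
            sum(manifest$counts$n) == nrow(events))
  list(events = events, manifest = manifest)
}

#' Lay out the standard cohort design
#'
#' Three animals per treatment group, both hemispheres processed separately,
#' both staining panels: 2 groups x 2 hemispheres x 2 panels x `n_animals`
#' samples.
#'
#' @param n_animals Animals per group.
#' @param n_events Cell events per sample.
#' @param tissue_mass_mg,beads_added Per-sample quantification inputs.
#' @param panels Panels to stain.
#' @return Design tibble, one row per sample.
#' @export
cohort_design <- function(n_animals = 3, n_events = 10000,
                          tissue_mass_mg = 20, beads_added = 5000,
                          panels = c("M1", "M2")) {
  if (n_animals < 1) abort("`n_animals` must be at least 1")
  grid <- tidyr::expand_grid(
    group = c("sham", "CCI"),
    animal = seq_len(n_animals),
    hemisphere = c("ipsilateral", "contralateral"),
    panel = panels)
  grid |>
    dplyr::mutate(
      animal_id = paste0(ifelse(.data$group == "sham", "S", "C"), .data$animal),
      n_events = n_events, tissue_mass_mg = tissue_mass_mg,
      beads_added = beads_added) |>
    dplyr::select("animal_id", "group", "hemisphere", "panel",
                  "n_events", "tissue_mass_mg", "beads_added")
}

#' Generate a full synthetic cohort
#'
#' One sample per design row; per-sample seeds and per-animal random
#' intercepts (location jitter shared across that animal's hemispheres and
#' panels) are derived deterministically from the master seed, so identical
#' calls are bit-identical end to end.
#'
#' @param design Tibble from [cohort_design()].
#' @param effects Tibble mapping condition and panel to [effect_model()],
#'   e.g. from [default_effects()] / [null_effects()] (rows for both panels
#'   are bound internally when the design uses both).
#' @param populations Optional function `panel -> population list`; defaults
#'   to [default_populations()].
#' @param seed Master seed.
#' @param animal_sigma Standard deviation of the per-animal random intercept
#'   (additive on the arcsinh scale for fluorescence, lognormal
#'   multiplicative for scatter). Set to 0 for exchangeable-event cohorts.
#' @param ... Passed to [simulate_sample()] (e.g. `cofactor`,
#'   `bead_recovery`).
#' @return A `cg_cohort` tibble: the design columns plus `sample_id`,
#'   `seed`, and list columns `events` and `manifest`.
#' @export
simulate_cohort <- function(design = cohort_design(),
                            effects = NULL,
                            populations = default_populations,
                            seed = 1L, animal_sigma = 0.05, ...) {
  if (nrow(design) == 0) abort("empty cohort design")
  if (is.null(effects)) {
    effects <- dplyr::bind_rows(lapply(unique(design$panel), default_effects))
  }

  animals <- unique(design$animal_id)
  all_ch <- unique(unlist(lapply(unique(design$panel), function(p) {
    generation_channels(populations(p))
  })))
  cls <- channel_class(all_ch)
  seeds <- derive_seeds(seed, nrow(design) + length(animals))
  sample_seeds <- seeds[seq_len(nrow(design))]
  animal_seeds <- seeds[nrow(design) + seq_along(animals)]

  offsets <- setNames(lapply(seq_along(animals), function(i) {
    withr::with_seed(animal_seeds[i], {
      eps <- rnorm(length(all_ch), 0, animal_sigma)
      names(eps) <- all_ch
      list(add = eps[cls != "scatter"], mult = exp(eps[cls == "scatter"]))
    })
  }), animals)

  rows <- purrr::pmap(
    c(design, list(.seed = sample_seeds, .row = seq_len(nrow(design)))),
    function(animal_id, group, hemisphere, panel, n_events, tissue_mass_mg,
             beads_added, .seed, .row) {
      eff <- effects |>
        dplyr::filter(.data$group == !!group,
                      .data$hemisphere == !!hemisphere,
                      .data$panel == !!panel)
      if (nrow(eff) != 1) {
        abort(sprintf("no unique effect for condition %s/%s panel %s",
                      group, hemisphere, panel))
      }
      sim <- simulate_sample(
        panel = panel, populations = populations(panel),
        effect = eff$effect[[1]], n_events = n_events,
        tissue_mass_mg = tissue_mass_mg, beads_added = beads_added,
        seed = .seed, animal_offsets = offsets[[animal_id]], ...)
      tibble::tibble(
        sample_id = sprintf("%s_%s_%s_%s", animal_id, group,
                            substr(hemisphere, 1, 5), panel),
        animal_id = animal_id, group = group, hemisphere = hemisphere,
        panel = panel, tissue_mass_mg = tissue_mass_mg,
        beads_added = beads_added, seed = .seed,
        events = list(sim$events), manifest = list(sim$manifest))
    })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("cg_cohort", class(out))
  attr(out, "master_seed") <- as.integer(seed)
  out
}

#' Draw correlated marker events for one population
#'
#' A light wrapper used for focused statistical experiments (differential
#' correlation, classifier nulls): `n` events over `markers` from a Gaussian
#' copula on the arcsinh scale, returned as a transformed-scale tibble.
#'
#' @param n Events.
#' @param markers Marker names.
#' @param location,scale Either scalars or named vectors per marker.
#' @param R Correlation matrix (default identity).
#' @param seed Integer seed.
#' @return Tibble of transformed intensities, `n` x `length(markers)`.
#' @export
simulate_marker_events <- function(n, markers, location = 2, scale = 0.75,
                                   R = NULL, seed = 1L) {
  mu <- if (length(location) == 1) setNames(rep(location, length(markers)),
                                            markers) else location[markers]
  sc <- if (length(scale) == 1) setNames(rep(scale, length(markers)),
                                         markers) else scale[markers]
  if (is.null(R)) {
    R <- diag(length(markers))
    dimnames(R) <- list(markers, markers)
  }
  check_correlation_matrix(R)
  X <- withr::with_seed(as.integer(seed),
                        rmvn_correlated(n, mu, sc, R[markers, markers]))
  colnames(X) <- markers
  out <- tibble::as_tibble(X)
  set_transform_state(set_transform_state(out, "compensated"), "transformed")
}

#' @export
print.cg_manifest <- function(x, ...) {
  cat("<cg_manifest>", sum(x$counts$n), "events, seed", x$seed, "\n")
  print(x$counts)
  invisible(x)
}
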