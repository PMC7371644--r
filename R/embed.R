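#' Downsample events uniformly without replacement
#'
#' @param events Event tibble (or anything with rows).
#' @param n Events to keep; all rows are returned when `n >= nrow`.
#' @param seed Integer seed (deterministic selection).
#' @return Sorted integer row indices.
#' @export
downsample_events <- function(events, n, seed = 1L) {
  total <- nrow(events)
  if (n < 1) abort("`n` must be at least 1")
  if (n >= total) return(seq_len(total))
  sort(withr::with_seed(as.integer(seed), sample.int(total, n)))
}

#' tSNE embedding of marker intensities
#'
#' Two-dimensional t-distributed stochastic neighbor embedding of the marker
#' channels (scatter channels are excluded by convention: the map should
#' reflect immunophenotype, not size). Deterministic for a fixed seed.
#'
#' @param features Event x marker tibble or matrix (transformed scale);
#'   must not contain scatter channels.
#' @param perplexity tSNE perplexity (events must exceed `3 * perplexity`).
#' @param n_iter Optimization iterations.
#' @param seed Integer seed.
#' @return A `cg_embedding` list: `coords` tibble (`tsne_1`, `tsne_2`),
#'   `channels`, `perplexity`, `n_iter`, `seed`, final `kl_divergence` and
#'   the per-50-iteration `kl_trace`.
#' @export
tsne_embed <- function(features, perplexity = 30, n_iter = 1000, seed = 1L) {
  X <- as.matrix(features)
  if (any(channel_class(colnames(X)) == "scatter")) {
    abort("scatter channels must be excluded from the embedding")
  }
  if (nrow(X) <= 3 * perplexity) {
    abort(sprintf("perplexity %g infeasible for %d events (need > 3x)",
                  perplexity, nrow(X)))
  }
  fit <- withr::with_seed(as.integer(seed),
    Rtsne::Rtsne(X, dims = 2, perplexity = perplexity, max_iter = n_iter,
                 pca = FALSE, check_duplicates = FALSE, verbose = FALSE,
                 num_threads = 1))
  structure(list(
    coords = tibble::tibble(tsne_1 = fit$Y[, 1], tsne_2 = fit$Y[, 2]),
    channels = colnames(X), perplexity = perplexity, n_iter = n_iter,
    seed = as.integer(seed),
    kl_divergence = fit$itercosts[length(fit$itercosts)],
    kl_trace = fit$itercosts), class = "cg_embedding")
}

#' @export
print.cg_embedding <- function(x, ...) {
  cat(sprintf("<cg_embedding> %d events, perplexity %g, KL %.3f\n",
              nrow(x$coords), x$perplexity, x$kl_divergence))
  invisible(x)
}

#' Binned density and mean-intensity maps over an embedding
#'
#' 2-D histogram of the embedding (cell density) and the per-bin mean of one
#' channel (marker overlay). Empty bins have undefined means and are `NA`.
#'
#' @param embedding `cg_embedding` (or a two-column coordinate tibble).
#' @param events Event tibble aligned row-for-row with the embedding.
#' @param channel Channel for the intensity overlay; `NULL` for density
#'   only.
#' @param bins Bins per axis.
#' @return Tibble with bin centers `x`, `y`, `count` and (when `channel` is
#'   given) `mean_intensity`.
#' @export
embedding_maps <- function(embedding, events = NULL, channel = NULL,
                           bins = 30) {
  coords <- if (inherits(embedding, "cg_embedding")) embedding$coords else
    tibble::as_tibble(embedding)
  if (!is.null(channel)) {
    if (is.null(events)) abort("`events` needed for an intensity overlay")
    if (nrow(events) != nrow(coords)) {
      abort("`events` must align row-for-row with the embedding")
    }
    if (!channel %in% names(events)) {
      abort(sprintf("channel '%s' not in events", channel))
    }
  }
  bx <- seq(min(coords[[1]]), max(coords[[1]]), length.out = bins + 1)
  by <- seq(min(coords[[2]]), max(coords[[2]]), length.out = bins + 1)
  ix <- pmin(findInterval(coords[[1]], bx, rightmost.closed = TRUE), bins)
  iy <- pmin(findInterval(coords[[2]], by, rightmost.closed = TRUE), bins)
  key <- (ix - 1) * bins + iy
  grid <- tidyr::expand_grid(bin_x = seq_len(bins), bin_y = seq_len(bins))
  counts <- tabulate(key, nbins = bins * bins)
  out <- grid |>
    dplyr::mutate(
      x = (bx[.data$bin_x] + bx[.data$bin_x + 1]) / 2,
      y = (by[.data$bin_y] + by[.data$bin_y + 1]) / 2,
      count = counts[(.data$bin_x - 1) * bins + .data$bin_y])
  if (!is.null(channel)) {
    sums <- rep(0, bins * bins)
    agg <- tapply(events[[channel]], key, mean)
    mean_int <- rep(NA_real_, bins * bins)
    mean_int[as.integer(names(agg))] <- as.vector(agg)
    out$mean_intensity <- mean_int[(out$bin_x - 1) * bins + out$bin_y]
  }
  out
}

#' Downsampled cohort embedding
#'
#' Downsamples each sample of one panel, pools the events, and embeds the
#' panel markers. Sample provenance is kept so density maps can be split by
#' condition.
#'
#' @param cohort Gated cohort.
#' @param panel Panel to embed.
#' @param n_per_sample Events kept per sample.
#' @param use `"microglia"` (gated events) or `"events"` (all events).
#' @param perplexity,n_iter,seed Passed to [tsne_embed()].
#' @return List with `embedding` (`cg_embedding`) and `events` (the pooled,
#'   downsampled events with `sample_id`, `group`, `hemisphere` columns).
#' @export
cohort_embedding <- function(cohort, panel = "M1", n_per_sample = 5000,
                             use = c("microglia", "events"),
                             perplexity = 30, n_iter = 1000, seed = 1L) {
  use <- match.arg(use)
  sub <- cohort[cohort$panel == panel, ]
  if (nrow(sub) == 0) abort(sprintf("no samples for panel %s", panel))
  seeds <- derive_seeds(seed, nrow(sub))
  pooled <- purrr::map_dfr(seq_len(nrow(sub)), function(i) {
    ev <- sub[[use]][[i]]
    idx <- downsample_events(ev, n_per_sample, seed = seeds[i])
    dplyr::bind_cols(
      tibble::tibble(sample_id = sub$sample_id[i], group = sub$group[i],
                     hemisphere = sub$hemisphere[i]),
      ev[idx, , drop = FALSE])
  })
  emb <- tsne_embed(pooled[panel_markers(panel)], perplexity = perplexity,
                    n_iter = n_iter, seed = seed)
  list(embedding = emb, events = pooled)
}
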