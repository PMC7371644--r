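test_that("rectangle, threshold and ratio gates follow the boundary conventions", {
  ev <- tibble::tibble(x = c(0.5, 2, 1), y = c(0.5, 2, 1))
  rect <- gate_rectangle("r", c("x", "y"), c(0, 1), c(0, 1))
  expect_identical(apply_gate(ev, rect), c(TRUE, FALSE, TRUE)) # boundary in

  thr <- gate_threshold("pos", "cd", 3.0, "above")
  expect_identical(apply_gate(tibble::tibble(cd = c(2.9, 3.0, 3.1)), thr),
                   c(FALSE, FALSE, TRUE)) # strictly greater

  expect_error(gate_rectangle("r", c("x", "y"), c(1, 0), c(0, 1)), "ordered")
  expect_error(gate_ratio_band("s", c("a", "b"), c(1, 1)), "lo < hi")
  expect_error(apply_gate(ev, gate_threshold("t", "missing", 1)), "missing")
})

test_that("polygon gate agrees with the rectangle oracle on random points", {
  withr::with_seed(4, {
    ev <- tibble::tibble(x = runif(1000, -1, 3), y = runif(1000, -1, 3))
  })
  square <- gate_polygon("sq", c("x", "y"),
                         rbind(c(0, 0), c(2, 0), c(2, 2), c(0, 2)))
  rect <- gate_rectangle("r", c("x", "y"), c(0, 2), c(0, 2))
  expect_identical(apply_gate(ev, square), apply_gate(ev, rect))
  expect_error(gate_polygon("p", c("x", "y"),
                            rbind(c(0, 0), c(1, 1), c(2, 2))), "collinear")
  # boundary point included under even-odd rule
  corner <- tibble::tibble(x = c(0, 2, 1), y = c(0, 2, 5))
  expect_identical(apply_gate(corner, square), c(TRUE, TRUE, FALSE))
})

test_that("singlet band keeps singlets and excludes constructed doublets", {
  ev <- tibble::tibble(FSC_A = c(100, 200, -5), FSC_H = c(95, 100, 4))
  expect_identical(singlet_mask(ev), c(TRUE, FALSE, FALSE))

  s <- one_sample(seed = 17)
  kept <- singlet_mask(s$events)
  dbl <- s$manifest$labels == "doublet"
  expect_gt(mean(!kept[dbl]), 0.95) # >= 95% of true doublets excluded
  cells <- s$manifest$labels %in% c("microglia", "infiltrate", "dead")
  expect_gt(mean(kept[cells]), 0.98)
})

test_that("viability threshold lands in the valley between live and dead", {
  s <- one_sample(seed = 19)
  ev <- transform_intensities(s$events)
  cells <- s$manifest$labels %in% c("microglia", "infiltrate", "dead")
  live <- viability_mask(ev[cells, ])
  truth_live <- s$manifest$labels[cells] != "dead"
  expect_gt(mean(live[truth_live]), 0.98)
  expect_gt(mean(!live[!truth_live]), 0.98)

  # unimodal all-live sample: falls back with a warning, everything kept
  all_live <- tibble::tibble(Viability = rnorm(500, 0.4, 0.1))
  expect_warning(kept <- viability_mask(all_live, fallback = 1.8),
                 "fallback")
  expect_all_true(kept)
  # dead-only sample: nothing kept
  dead <- tibble::tibble(Viability = rnorm(500, 3.2, 0.1))
  expect_warning(kept_dead <- viability_mask(dead, fallback = 1.8))
  expect_all_true(!kept_dead)
})

test_that("strategy recovers the manifest microglia count and stays nested", {
  s <- one_sample(seed = 23, n_events = 8000)
  ev <- transform_intensities(s$events)
  g <- run_strategy(ev, default_gating_strategy())
  truth <- sum(s$manifest$labels == "microglia")
  got <- g$populations$events[g$populations$node == "microglia"]
  expect_lt(abs(got - truth) / truth, 0.05)

  # nestedness along every path + gate idempotence
  for (node in g$populations$node) {
    parent <- g$populations$parent[g$populations$node == node]
    pmask <- if (parent == "all") rep(TRUE, nrow(ev)) else g$masks[, parent]
    expect_all_true(pmask[g$masks[, node]], info = node)
  }
  gate <- default_gating_strategy()$nodes[[2]]$gate
  once <- apply_gate(ev, gate)
  expect_identical(apply_gate(ev, gate, once), once)

  # bead node disjoint from the cell node
  expect_identical(sum(g$masks[, "beads"] & g$masks[, "cells"]), 0L)

  empty <- run_strategy(ev[0, ], default_gating_strategy())
  expect_all_true(empty$populations$events == 0)
})

test_that("strategy construction validates names and parent order", {
  expect_error(gating_strategy(list(
    list(name = "a", parent = "all", gate = gate_threshold("a", "x", 1)),
    list(name = "a", parent = "all", gate = gate_threshold("a", "x", 1)))),
    "unique")
  expect_error(gating_strategy(list(
    list(name = "a", parent = "b", gate = gate_threshold("a", "x", 1)))),
    "parent")
})

test_that("absolute counts follow the bead formula exactly and linearly", {
  r <- absolute_count(5000, 1000, 10000, 50)
  expect_equal(r$cells_per_mg, 1000)
  expect_equal(absolute_count(0, 1000, 10000, 50)$cells_per_mg, 0)
  expect_equal(absolute_count(5000, 1000, 20000, 50)$cells_per_mg, 2000)
  expect_equal(absolute_count(10000, 1000, 10000, 50)$cells_per_mg, 2000)
  expect_equal(absolute_count(5000, 2000, 10000, 50)$cells_per_mg, 500)
  expect_equal(absolute_count(5000, 1000, 10000, 100)$cells_per_mg, 500)
  expect_error(absolute_count(5000, 0, 10000, 50), "bead")
})

test_that("fold change vs reference reproduces the hand-computed ratios", {
  counts <- tibble::tibble(
    group = c("CCI", "sham", "sham", "CCI"),
    hemisphere = c("ipsilateral", "ipsilateral", "contralateral",
                   "contralateral"),
    cells_per_mg = c(1600, 100, 100, 100))
  expect_equal(fold_change_vs_reference(counts), 16)
  counts$cells_per_mg <- rep(7, 4)
  expect_equal(fold_change_vs_reference(counts), 1)
  expect_error(fold_change_vs_reference(counts, reference = counts[0, 1:2]),
               "empty")
  counts$cells_per_mg <- c(1, 0, 0, 0)
  expect_error(fold_change_vs_reference(counts), "zero")
})

test_that("cohort gating recovers every population with high F1", {
  co <- tiny_cohort()
  f1 <- purrr::map_dfr(seq_len(nrow(co)), function(i) {
    population_f1(co$gating[[i]], co$manifest[[i]])
  })
  worst <- f1 |>
    dplyr::group_by(.data$population) |>
    dplyr::summarise(f1 = min(.data$f1, na.rm = TRUE))
  expect_all_true(worst$f1 >= 0.9, info = paste(worst$population, worst$f1))
})
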