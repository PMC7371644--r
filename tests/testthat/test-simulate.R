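test_that("identical seeds and parameters give bit-identical samples", {
  a <- simulate_sample(n_events = 500, beads_added = 200, seed = 7)
  b <- simulate_sample(n_events = 500, beads_added = 200, seed = 7)
  expect_identical(a$events, b$events)
  expect_identical(a$manifest$labels, b$manifest$labels)
  c <- simulate_sample(n_events = 500, beads_added = 200, seed = 8)
  expect_false(identical(a$events, c$events))
})

test_that("manifest counts match realized events exactly and follow the binomial", {
  pops <- default_populations("M1", microglia_fraction = 0.2)
  s <- simulate_sample(populations = pops, n_events = 10000,
                       beads_added = 100, seed = 3)
  expect_identical(sum(s$manifest$counts$n), nrow(s$events))
  n_mg <- s$manifest$counts$n[s$manifest$counts$population == "microglia"]
  expect_lt(abs(n_mg - 2000), 3 * sqrt(10000 * 0.2 * 0.8))
  # realized label tabulation equals the manifest count table
  expect_identical(as.integer(table(s$manifest$labels)[s$manifest$counts$population]),
                   s$manifest$counts$n)
})

test_that("channel shifts move the transformed microglia median by the shift", {
  R <- marker_correlation(panel_markers("M1"))
  shifted <- effect_model("CCI", "ipsilateral", 1, c(CD32 = 0.8), R)
  sham <- effect_model("sham", "ipsilateral", correlation_matrix = R)
  pops <- default_populations("M1", microglia_fraction = 0.5)
  med_cd32 <- function(effect, seed) {
    s <- simulate_sample(populations = pops, effect = effect,
                         n_events = 20000, beads_added = 100, seed = seed)
    ev <- transform_intensities(s$events)
    median(ev$CD32[s$manifest$labels == "microglia"])
  }
  diff <- med_cd32(shifted, 11) - med_cd32(sham, 12)
  expect_lt(abs(diff - 0.8), 0.05)
})

test_that("population and effect validation rejects inconsistent inputs", {
  pops <- default_populations("M1")
  pops[[1]]$base_fraction <- 0.5 # fractions no longer sum to 1
  expect_error(simulate_sample(populations = pops, seed = 1), "sum to 1")

  bad_R <- matrix(c(1, 0.9, 0.9, 0.9, 1, -0.9, 0.9, -0.9, 1), 3,
                  dimnames = rep(list(c("CD45", "CD11bc", "P2y12")), 2))
  expect_error(check_correlation_matrix(bad_R), "positive semi-definite")
  expect_error(effect_model("CCI", "ipsilateral",
                            correlation_matrix = bad_R), "semi-definite")
  expect_error(effect_model("sham", "ipsilateral", 2), "sham")
  expect_error(effect_model("sham", "ipsilateral",
                            channel_shifts = c(CD45 = 1)), "sham")
  expect_error(population_spec("x", 0.1, c(CD45 = 1), c(CD45 = -1)),
               "positive")
  expect_error(simulate_sample(n_events = 50, seed = 1), "at least 100")
})

test_that("realized per-channel medians converge to specified locations", {
  s <- simulate_sample(n_events = 20000, beads_added = 100, seed = 21)
  ev <- transform_intensities(s$events)
  pops <- default_populations("M1")
  names(pops) <- vapply(pops, `[[`, character(1), "name")
  for (pop in c("microglia", "infiltrate", "debris")) {
    mask <- s$manifest$labels == pop
    n <- sum(mask)
    spec <- pops[[pop]]
    for (ch in c("SSC_A", "CD45", "P2y12", "CD32")) {
      err <- abs(median(ev[[ch]][mask]) - spec$locations[[ch]])
      expect_lt(err, 3 * spec$scales[[ch]] / sqrt(n) + 0.02)
    }
  }
})

test_that("copula-injected marker correlation is recovered within 0.05", {
  mk <- panel_markers("M1")
  R <- marker_correlation(mk, boost_markers = c("CD45", "CD32"), boost = 0.6)
  eff <- effect_model("CCI", "ipsilateral", 1, correlation_matrix = R)
  s <- simulate_sample(populations = default_populations("M1", 0.5),
                       effect = eff, n_events = 25000, beads_added = 100,
                       seed = 9)
  ev <- transform_intensities(s$events)
  mg <- ev[s$manifest$labels == "microglia", mk]
  emp <- pearson_matrix(mg)
  expect_lt(max(abs(emp - R)), 0.05)
})

test_that("doublets double FSC area but not height", {
  s <- one_sample(seed = 13)
  raw <- s$events
  dbl <- s$manifest$labels == "doublet"
  sing <- s$manifest$labels %in% c("microglia", "infiltrate")
  expect_gt(median(raw$FSC_A[dbl]) / median(raw$FSC_A[sing]), 1.8)
  expect_lt(median(raw$FSC_H[dbl]) / median(raw$FSC_H[sing]), 1.4)
})

test_that("cohort layout, determinism, and animal intercepts behave", {
  d <- cohort_design(n_events = 300, beads_added = 100)
  expect_identical(nrow(d), 24L) # 3 animals x 2 groups x 2 hemi x 2 panels
  co1 <- simulate_cohort(d, seed = 5)
  co2 <- simulate_cohort(d, seed = 5)
  expect_identical(co1$events, co2$events)
  expect_identical(co1$seed, co2$seed)
  expect_error(simulate_cohort(d[0, ], seed = 1), "empty")

  # same animal shares its intercept across hemispheres; animals differ
  co3 <- simulate_cohort(cohort_design(n_events = 5000, beads_added = 100,
                                       panels = "M1"),
                         seed = 5, animal_sigma = 0.3)
  m <- gate_cohort(prepare_cohort(co3))
  sham <- m[m$group == "sham" & m$panel == "M1", ]
  mfi <- vapply(sham$microglia, function(ev) median(ev$CD45), numeric(1))
  animal_spread <- sd(tapply(mfi, sham$animal_id, mean))
  expect_gt(animal_spread, 0.05)
})

test_that("simulate_marker_events hits requested correlation and location", {
  mk <- c("A", "B", "C")
  R <- matrix(c(1, 0.6, 0, 0.6, 1, 0, 0, 0, 1), 3, dimnames = list(mk, mk))
  ev <- simulate_marker_events(10000, mk, location = 1.5, scale = 0.5,
                               R = R, seed = 2)
  expect_lt(abs(cor(ev$A, ev$B) - 0.6), 0.05)
  expect_lt(abs(mean(ev$C) - 1.5), 0.05)
  expect_identical(ev, simulate_marker_events(10000, mk, location = 1.5,
                                              scale = 0.5, R = R, seed = 2))
})
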