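test_that("MFI follows the median/mean conventions", {
  expect_equal(compute_mfi(c(1, 2, 3)), 2)
  expect_equal(compute_mfi(c(1, 2, 3, 10)), 2.5) # midpoint for even n
  expect_equal(compute_mfi(c(1, 2, 3, 10), "mean"), 4)
  expect_error(compute_mfi(numeric()), "empty")
})

test_that("Mann-Whitney U matches enumeration on the textbook example", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6), alternative = "less")
  expect_equal(r$U, 0)
  expect_equal(r$p_value, 1 / 20) # one of C(6,3) = 20 rank assignments
  expect_identical(r$method, "exact")

  x <- c(2, 2, 5, 5, 9)
  same <- suppressWarnings(mann_whitney_u(x, x))
  expect_equal(same$U, length(x)^2 / 2)
  expect_gte(same$p_value, 0.99)

  expect_warning(deg <- mann_whitney_u(c(1, 1), c(1, 1)), "degenerate")
  expect_equal(deg$p_value, 1)
  expect_error(mann_whitney_u(numeric(), 1), "non-empty")
})

test_that("Mann-Whitney agrees with the brute-force oracle on random instances", {
  withr::with_seed(101, {
    for (i in 1:200) {
      n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
      vals <- sample(seq_len(50), n1 + n2) # distinct: exact mode
      x <- vals[seq_len(n1)]; y <- vals[-seq_len(n1)]
      alt <- sample(c("two.sided", "greater", "less"), 1)
      got <- mann_whitney_u(x, y, alt)
      expect_equal(got$U, mw_u_oracle(x, y))
      expect_lt(abs(got$p_value - mw_p_oracle(x, y, alt)), 1e-9)
    }
  })
})

test_that("Mann-Whitney is invariant under strictly monotone transforms", {
  withr::with_seed(5, {
    x <- rnorm(40); y <- rnorm(35, 0.5)
  })
  a <- mann_whitney_u(x, y)
  b <- mann_whitney_u(exp(x), exp(y))
  expect_equal(a$U, b$U)
  expect_equal(a$p_value, b$p_value)
})

test_that("BH step-up matches its definition and a brute-force oracle", {
  r <- bh_fdr(c(0.01, 0.02, 0.03, 0.04, 0.2), 0.05)
  expect_identical(sum(r$rejected), 4L)
  expect_identical(sum(bh_fdr(rep(1, 10), 0.05)$rejected), 0L)
  expect_true(bh_fdr(0.04, 0.05)$rejected) # m = 1 reduces to p <= q
  expect_identical(nrow(bh_fdr(numeric(), 0.05)), 0L)
  expect_error(bh_fdr(0.5, 1.5), "0, 1")
  expect_error(bh_fdr(c(0.5, 2), 0.05), "0, 1")

  withr::with_seed(303, {
    for (i in 1:200) {
      m <- sample(1:25, 1)
      p <- round(runif(m), 3)
      q <- sample(c(0.01, 0.05, 0.1, 0.2), 1)
      got <- bh_fdr(p, q)
      expect_identical(got$rejected, bh_reject_oracle(p, q))
      # rejections grow monotonically with q
      expect_all_true(got$rejected <= bh_fdr(p, min(0.99, q * 2))$rejected)
    }
  })
})

test_that("marker screen recovers injected directions on a small cohort", {
  co <- simulate_cohort(
    cohort_design(n_events = 4000, beads_added = 500),
    seed = 31, animal_sigma = 0)
  co <- gate_cohort(prepare_cohort(co))
  scr <- marker_screen(co)
  ipsi <- scr[scr$hemisphere == "ipsilateral", ]
  dir <- setNames(ipsi$direction, ipsi$parameter)
  expect_identical(unname(dir[c("CD45", "CD32", "CD163", "FSC_A", "SSC_A")]),
                   rep("up", 5))
  expect_identical(unname(dir[c("P2y12", "CD86", "RT1B")]), rep("down", 3))
  expect_identical(unname(dir["CD200R"]), "none")
  expect_all_true(scr$p_value >= 1e-300)
  expect_identical(unique(scr$scale), "arcsinh")
})

test_that("animal-level screen mode tests per-animal MFIs", {
  co <- tiny_cohort()
  scr <- marker_screen(co, unit = "animal")
  expect_all_true(scr$n_cci == 3 & scr$n_sham == 3)
  expect_all_true(scr$p_value > 1e-4) # n = 3 per group cannot reach tiny p
})

test_that("QQ curves sit on the identity for equal samples and track shifts", {
  withr::with_seed(8, x <- rnorm(5000))
  same <- qq_curve(x, x)
  expect_equal(same$median_shift, 0)
  expect_equal(same$signed_area, 0)
  expect_all_true(abs(same$curve$q_y - same$curve$q_x) < 1e-12)

  shift <- qq_curve(x, x + 2)
  expect_lt(abs(shift$median_shift - 2), 0.05)

  withr::with_seed(9, y <- rnorm(5000, -1)) # stochastically smaller
  expect_lt(qq_curve(x, y)$signed_area, 0)
  expect_all_true(diff(qq_curve(x, y, 25)$curve$q_x) >= 0)
  expect_error(qq_curve(x, x, n_probes = 2), "at least 3")
})

test_that("cohort QQ summaries match the injected shift directions", {
  co <- tiny_cohort()
  qq <- cohort_qq(co)
  ipsi <- qq[qq$hemisphere == "ipsilateral", ]
  up <- ipsi$median_shift[ipsi$parameter %in% c("CD45", "CD32", "CD163")]
  down <- ipsi$median_shift[ipsi$parameter %in% c("P2y12", "CD86", "RT1B")]
  expect_all_true(up > 0)
  expect_all_true(down < 0)
})
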