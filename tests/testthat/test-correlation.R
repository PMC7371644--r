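test_that("Pearson matrix handles perfect and degenerate relationships", {
  ev <- tibble::tibble(a = c(1, 2, 3, 4, 5), b = c(1, 2, 3, 4, 5) * 2 + 1,
                       c = -c(1, 2, 3, 4, 5), d = rep(3, 5))
  expect_warning(R <- pearson_matrix(ev), "zero-variance")
  expect_equal(R["a", "b"], 1)
  expect_equal(R["a", "c"], -1)
  expect_true(all(is.na(R["d", ])))
  expect_equal(unname(diag(R)[1:3]), rep(1, 3))
  expect_error(pearson_matrix(ev[1:3, ]), "at least 4")
})

test_that("Fisher z and Cohen's q follow their closed forms", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5 * log(3))
  withr::with_seed(6, r <- runif(20, -0.99, 0.99))
  expect_equal(fisher_z(-r), -fisher_z(r)) # odd symmetry
  expect_error(fisher_z(1), "clamp")
  expect_warning(z <- fisher_z(1, clamp = TRUE), "clamp")
  expect_lt(z, 15)

  expect_equal(cohens_q(0.68, 0.68), 0)
  expect_equal(cohens_q(0.68, 0.30), atanh(0.68) - atanh(0.30))
  expect_equal(round(cohens_q(0.68, 0.30), 4), 0.5196)
  expect_equal(cohens_q(0.5, -0.5), 2 * atanh(0.5))
  expect_equal(round(cohens_q(0.5, -0.5), 4), 1.0986)
  expect_equal(cohens_q(0.3, 0.7), cohens_q(0.7, 0.3)) # symmetric
})

test_that("Fisher-z difference test matches the closed form and its null", {
  same <- correlation_difference_test(0.4, 100, 0.4, 200)
  expect_equal(same$z_statistic, 0)
  expect_equal(same$p_value, 0.5)

  r <- correlation_difference_test(0.68, 103, 0.30, 103)
  expect_equal(r$z_statistic, (atanh(0.68) - atanh(0.30)) / sqrt(2 / 100))
  expect_equal(round(r$z_statistic, 3), 3.674)
  expect_equal(r$p_value, pnorm(r$z_statistic, lower.tail = FALSE))
  expect_lt(abs(r$p_value - 1.2e-4), 2e-5)
  expect_error(correlation_difference_test(0.5, 3, 0.5, 100), "exceed 3")

  # type-I rate at nominal 0.05 under equal true correlations
  withr::with_seed(77, {
    mk <- c("A", "B")
    R <- matrix(c(1, 0.3, 0.3, 1), 2, dimnames = list(mk, mk))
    rejections <- vapply(1:300, function(i) {
      x <- simulate_marker_events(2000, mk, R = R, seed = 1000 + i)
      y <- simulate_marker_events(2000, mk, R = R, seed = 5000 + i)
      correlation_difference_test(cor(x$A, x$B), 2000,
                                  cor(y$A, y$B), 2000)$p_value < 0.05
    }, logical(1))
  })
  rate <- mean(rejections)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 300))
})

test_that("differential screen flags the constructed pair and composes", {
  mk <- c("A", "B")
  R_inj <- matrix(c(1, 0.9, 0.9, 1), 2, dimnames = list(mk, mk))
  inj <- simulate_marker_events(1000, mk, R = R_inj, seed = 21)
  sham <- simulate_marker_events(1000, mk, seed = 22)
  scr <- differential_correlation_screen(inj, sham)
  expect_identical(nrow(scr$pairs), 1L)
  expect_true(scr$pairs$fdr_significant_higher)
  expect_equal(scr$fraction_significantly_higher, 1)

  # oracle decomposition: screen == pearson -> q -> z test -> BH, pairwise
  mk5 <- paste0("M", 1:5)
  R5 <- marker_correlation(mk5, boost_markers = c("M1", "M2"), boost = 0.5)
  inj5 <- simulate_marker_events(3000, mk5, R = R5, seed = 31)
  sham5 <- simulate_marker_events(3000, mk5, seed = 32)
  scr5 <- differential_correlation_screen(inj5, sham5)
  R1 <- pearson_matrix(inj5); R2 <- pearson_matrix(sham5)
  manual <- purrr::pmap_dfr(scr5$pairs[c("marker_1", "marker_2")],
    function(marker_1, marker_2) {
      tibble::tibble(
        q = cohens_q(R1[marker_1, marker_2], R2[marker_1, marker_2]),
        p = correlation_difference_test(R1[marker_1, marker_2], 3000,
                                        R2[marker_1, marker_2], 3000)$p_value)
    })
  expect_equal(scr5$pairs$cohens_q, manual$q)
  expect_equal(scr5$pairs$p_value, manual$p)
  expect_identical(scr5$pairs$fdr_significant_higher & TRUE,
                   bh_reject_oracle(manual$p, 0.01) &
                     scr5$pairs$rho_injury > scr5$pairs$rho_sham)

  # heat map symmetric with zero diagonal
  expect_identical(scr5$q_matrix, t(scr5$q_matrix))
  expect_equal(unname(diag(scr5$q_matrix)), rep(0, 5))
})

test_that("screen is null-calibrated and affine-invariant", {
  mk <- paste0("M", 1:4)
  R <- marker_correlation(mk, base = 0.2)
  inj <- simulate_marker_events(4000, mk, R = R, seed = 41)
  sham <- simulate_marker_events(4000, mk, R = R, seed = 42)
  scr <- differential_correlation_screen(inj, sham)
  expect_lte(sum(scr$pairs$fdr_significant_higher), 1) # null: ~0 flags

  rescaled <- dplyr::mutate(inj, M1 = 3 * .data$M1 + 7, M3 = 0.2 * .data$M3)
  scr2 <- differential_correlation_screen(rescaled, sham)
  expect_equal(scr2$pairs$rho_injury, scr$pairs$rho_injury)
  expect_error(differential_correlation_screen(inj[1:3, ], sham), "at least 4")
  expect_error(differential_correlation_screen(inj["M1"], sham["M1"]),
               "at least 2")
})

test_that("cohort correlation fractions separate ipsi from contra", {
  co <- tiny_cohort()
  cc <- cohort_correlation(co)
  ipsi <- cc$fraction_significantly_higher[cc$hemisphere == "ipsilateral"]
  contra <- cc$fraction_significantly_higher[cc$hemisphere == "contralateral"]
  expect_all_true(ipsi >= 0.4)
  expect_all_true(contra <= 0.2)
})
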