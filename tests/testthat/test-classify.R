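test_that("ROC AUC follows the rank formula and the U identity", {
  expect_equal(roc_auc(c(1, 2, 10, 20), c(0, 0, 1, 1)), 1)
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")
  expect_error(roc_auc(1:3, c(1, 1)), "equal length")

  withr::with_seed(11, {
    for (i in 1:100) {
      n1 <- sample(3:20, 1); n0 <- sample(3:20, 1)
      s <- c(rnorm(n1, 0.3), rnorm(n0))
      labels <- rep(c(TRUE, FALSE), c(n1, n0))
      u <- mann_whitney_u(s[labels], s[!labels])$U
      expect_equal(roc_auc(s, labels), u / (n1 * n0))
    }
    # invariant under strictly monotone transform of the scores
    s <- rnorm(50); l <- rep(c(TRUE, FALSE), 25)
    expect_equal(roc_auc(exp(s), l), roc_auc(s, l))
    # independent cross-check against pROC
    expect_equal(roc_auc(s, l),
                 as.numeric(pROC::auc(pROC::roc(l, s, direction = "<",
                                                quiet = TRUE))))
  })
})

test_that("cross-validated AUC is near 0.5 when labels are independent", {
  withr::with_seed(12, {
    X <- matrix(rnorm(800 * 4), 800, 4,
                dimnames = list(NULL, paste0("M", 1:4)))
    y <- rep(c(TRUE, FALSE), 400)
  })
  res <- crossval_discriminate(X, y, "logistic", k = 5, runs = 3, seed = 2)
  expect_gt(res$auc_mean, 0.45)
  expect_lt(res$auc_mean, 0.55)
  expect_equal(res$auc_mean, mean(res$run_aucs$auc))
  expect_equal(res$auc_sd, sd(res$run_aucs$auc))
  expect_identical(nrow(res$fold_aucs), 15L)
})

test_that("label permutation drives every classifier to chance", {
  withr::with_seed(13, {
    X <- matrix(rnorm(1000 * 3), 1000, 3,
                dimnames = list(NULL, paste0("M", 1:3)))
    X[1:500, 1] <- X[1:500, 1] + 2 # real signal
    y_perm <- sample(rep(c(TRUE, FALSE), 500)) # permuted labels
  })
  for (cl in c("logistic", "random_forest", "rbf_svm")) {
    res <- crossval_discriminate(X, y_perm, cl, k = 5, runs = 2, seed = 3)
    expect_lt(abs(res$auc_mean - 0.5), 0.05)
  }
})

test_that("separable classes give high AUC and sensible contributions", {
  withr::with_seed(14, {
    X <- matrix(rnorm(600 * 3), 600, 3,
                dimnames = list(NULL, c("CD45", "CD32", "CD200R")))
    y <- rep(c(TRUE, FALSE), 300)
    X[y, "CD45"] <- X[y, "CD45"] + 1.5
  })
  res <- crossval_discriminate(X, y, "logistic", k = 5, runs = 3, seed = 4)
  expect_gt(res$auc_mean, 0.8)
  contrib <- res$feature_contributions
  expect_gt(contrib[["CD45"]], contrib[["CD200R"]])
  td <- tidy(res)
  expect_identical(td$term, colnames(X))
  expect_identical(glance(res)$auc_mean, res$auc_mean)

  # duplicated feature column leaves the ridge AUC essentially unchanged
  X2 <- cbind(X, CD45b = X[, "CD45"])
  res2 <- crossval_discriminate(X2, y, "logistic", k = 5, runs = 3, seed = 4)
  expect_lt(abs(res2$auc_mean - res$auc_mean), 0.01)
})

test_that("fold count shrinks with a warning when a class is tiny", {
  withr::with_seed(15, {
    X <- matrix(rnorm(30 * 2), 30, 2, dimnames = list(NULL, c("a", "b")))
    y <- rep(c(TRUE, FALSE), c(6, 24))
  })
  expect_warning(res <- crossval_discriminate(X, y, "logistic", k = 10,
                                              runs = 2, seed = 5),
                 "folds")
  expect_lte(res$k, 3)
})

test_that("propensity scores are probabilities that track the injury class", {
  withr::with_seed(16, {
    X <- matrix(rnorm(500 * 2), 500, 2, dimnames = list(NULL, c("m1", "m2")))
    y <- rep(c(TRUE, FALSE), 250)
    X[y, ] <- X[y, ] + 0.9
  })
  res <- crossval_discriminate(X, y, "logistic", k = 5, runs = 2, seed = 6)
  ps <- propensity_scores(res, X)
  expect_identical(nrow(ps), 500L)
  expect_all_true(ps$propensity >= 0 & ps$propensity <= 1)
  expect_gt(roc_auc(ps$propensity, y), 0.7)

  # event at the feature midpoint of a symmetric balanced set scores ~0.5
  mid <- matrix(colMeans(X), 1, dimnames = list(NULL, c("m1", "m2")))
  expect_lt(abs(propensity_scores(res, mid)$propensity - 0.5), 0.05)
  expect_error(propensity_scores(res, X[, 1, drop = FALSE]), "channels")
})

test_that("cohort discrimination separates ipsilateral injury from sham", {
  co <- tiny_cohort()
  cd <- cohort_discriminate(co, "ipsilateral", classifiers = "logistic",
                            n_per_class = 600, k = 5, runs = 3, seed = 9)
  expect_all_true(cd$auc_mean > 0.75)
  expect_identical(nrow(cd), 2L) # one per panel
})
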