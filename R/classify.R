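#' Area under the ROC curve by the rank formula
#'
#' `AUC = P(score_pos > score_neg) + P(tie) / 2`, computed with midranks, so
#' it equals the Mann-Whitney U statistic divided by `n_pos * n_neg`.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (logical, 0/1, or a factor/character with the
#'   positive class given by `positive`).
#' @param positive Positive class label for non-logical input.
#' @return AUC in `[0, 1]`.
#' @examples
#' roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)) # 0.75
#' @export
roc_auc <- function(scores, labels, positive = NULL) {
  if (length(scores) != length(labels)) {
    abort("`scores` and `labels` must have equal length")
  }
  pos <- if (is.logical(labels)) labels
  else if (is.numeric(labels)) labels == 1
  else labels == (positive %||% sort(unique(as.character(labels)))[1])
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) abort("both classes must be present")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

standardize_train_test <- function(train, test) {
  mu <- colMeans(train)
  s <- apply(train, 2, sd)
  s[s == 0] <- 1
  list(train = sweep(sweep(train, 2, mu), 2, s, `/`),
       test = sweep(sweep(test, 2, mu), 2, s, `/`),
       center = mu, scale = s)
}

fit_score <- function(classifier, train, y_train, test, seed,
                      ridge_lambda = 0.01, num_trees = 200) {
  switch(
    classifier,
    logistic = {
      fit <- glmnet::glmnet(train, factor(y_train, levels = c(FALSE, TRUE)),
                            family = "binomial", alpha = 0,
                            lambda = ridge_lambda, standardize = FALSE)
      list(scores = as.vector(predict(fit, test, type = "response")),
           importance = setNames(abs(as.vector(fit$beta)),
                                 rownames(fit$beta)))
    },
    random_forest = {
      fit <- ranger::ranger(
        x = as.data.frame(train), y = factor(y_train),
        num.trees = num_trees, probability = TRUE, seed = seed,
        importance = "permutation", num.threads = 1)
      pr <- predict(fit, as.data.frame(test), num.threads = 1)$predictions
      list(scores = pr[, "TRUE"], importance = fit$variable.importance)
    },
    rbf_svm = {
      yf <- factor(y_train, levels = c(TRUE, FALSE)) # decision > 0 => TRUE
      fit <- e1071::svm(train, yf, kernel = "radial", cost = 1,
                        scale = FALSE)
      dv <- attr(predict(fit, test, decision.values = TRUE),
                 "decision.values")[, 1]
      imp <- rep(NA_real_, ncol(train)) |> setNames(colnames(train))
      list(scores = dv, importance = imp, fit = fit)
    },
    abort(sprintf("unknown classifier '%s'", classifier)))
}

stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Cross-validated discrimination of two conditions from marker intensities
#'
#' Stratified k-fold cross-validation repeated over independently re-split
#' runs. Features are standardized within training folds only; per-run AUC
#' is the mean over folds and the headline `auc_mean`/`auc_sd` are the mean
#' and standard deviation over the run-level means. Feature contributions
#' are mean absolute standardized ridge coefficients (logistic) or ranger's
#' permutation importance (random forest); the RBF-SVM reports scores only.
#' When a class is too small for `k` folds, `k` is reduced with a warning.
#'
#' @param features Event x marker matrix or tibble (transformed scale).
#' @param labels Logical/binary vector; `TRUE`/1 is the positive (injury)
#'   class.
#' @param classifier `"logistic"`, `"random_forest"` or `"rbf_svm"`.
#' @param k Folds (default 10).
#' @param runs Repeated CV runs with different splits (default 10).
#' @param seed Integer seed controlling all splits and tree randomness.
#' @param ridge_lambda L2 penalty of the logistic model.
#' @return A `cg_classifier` list: `classifier`, `auc_mean`, `auc_sd`,
#'   `run_aucs`, `fold_aucs` tibble, `feature_contributions`, and the final
#'   logistic model refit on all data (for propensity scores).
#' @export
crossval_discriminate <- function(features, labels,
                                  classifier = c("logistic", "random_forest",
                                                 "rbf_svm"),
                                  k = 10, runs = 10, seed = 1L,
                                  ridge_lambda = 0.01) {
  classifier <- match.arg(classifier)
  X <- as.matrix(features)
  y <- if (is.logical(labels)) labels else labels == 1
  if (length(y) != nrow(X)) abort("labels must match feature rows")
  if (length(unique(y)) != 2) abort("both classes must be present")
  n_min <- min(table(y))
  if (n_min < 2 * k) {
    k_new <- max(2, floor(n_min / 2))
    warn(sprintf("smallest class (%d events) too small for %d folds; using %d",
                 n_min, k, k_new))
    k <- k_new
  }

  fold_rows <- list()
  contrib <- NULL
  run_seeds <- derive_seeds(seed, runs)
  for (r in seq_len(runs)) {
    withr::with_seed(run_seeds[r], {
      fold <- stratified_folds(y, k)
      for (f in seq_len(k)) {
        tr <- fold != f
        st <- standardize_train_test(X[tr, , drop = FALSE],
                                     X[!tr, , drop = FALSE])
        fs <- fit_score(classifier, st$train, y[tr], st$test,
                        seed = run_seeds[r] + f, ridge_lambda = ridge_lambda)
        fold_rows[[length(fold_rows) + 1]] <- tibble::tibble(
          run = r, fold = f, auc = roc_auc(fs$scores, y[!tr]))
        contrib <- if (is.null(contrib)) fs$importance else
          contrib + fs$importance
      }
    })
  }
  fold_aucs <- dplyr::bind_rows(fold_rows)
  run_aucs <- fold_aucs |>
    dplyr::group_by(.data$run) |>
    dplyr::summarise(auc = mean(.data$auc), .groups = "drop")

  # full-data logistic refit for propensity scoring
  st <- standardize_train_test(X, X)
  full_fit <- glmnet::glmnet(st$train, factor(y, levels = c(FALSE, TRUE)),
                             family = "binomial", alpha = 0,
                             lambda = ridge_lambda, standardize = FALSE)
  structure(list(
    classifier = classifier,
    auc_mean = mean(run_aucs$auc), auc_sd = sd(run_aucs$auc),
    run_aucs = run_aucs, fold_aucs = fold_aucs,
    feature_contributions = contrib / (k * runs),
    k = k, runs = runs, seed = as.integer(seed),
    channels = colnames(X),
    model = list(fit = full_fit, center = st$center, scale = st$scale)),
    class = "cg_classifier")
}

#' @export
print.cg_classifier <- function(x, ...) {
  cat(sprintf("<cg_classifier> %s: AUC %.3f +- %.4f (%d-fold x %d runs)\n",
              x$classifier, x$auc_mean, x$auc_sd, x$k, x$runs))
  invisible(x)
}

#' @export
tidy.cg_classifier <- function(x, ...) {
  tibble::tibble(classifier = x$classifier,
                 term = names(x$feature_contributions),
                 contribution = unname(x$feature_contributions))
}

#' @export
glance.cg_classifier <- function(x, ...) {
  tibble::tibble(classifier = x$classifier, auc_mean = x$auc_mean,
                 auc_sd = x$auc_sd, k = x$k, runs = x$runs)
}

#' Per-cell propensity scores from a trained logistic model
#'
#' The fitted logistic model's predicted probability of the injury class for
#' each event: a per-cell propensity to deviate from sham. Monotone in the
#' linear predictor and always in `[0, 1]`.
#'
#' @param result `cg_classifier` fitted with `classifier = "logistic"` (any
#'   classifier result carries the logistic refit used here).
#' @param events Event tibble or matrix with the training channels.
#' @return Tibble with `event` index and `propensity`.
#' @export
propensity_scores <- function(result, events) {
  X <- as.matrix(if (is.data.frame(events)) events[, result$channels,
                                                   drop = FALSE] else events)
  missing <- setdiff(result$channels, colnames(X))
  if (length(missing)) {
    abort(sprintf("events lack training channels: %s",
                  paste(missing, collapse = ", ")))
  }
  X <- X[, result$channels, drop = FALSE]
  Xs <- sweep(sweep(X, 2, result$model$center), 2, result$model$scale, `/`)
  p <- as.vector(predict(result$model$fit, Xs, type = "response"))
  tibble::tibble(event = seq_len(nrow(X)), propensity = p)
}

#' Classifier panel over a gated cohort
#'
#' For each panel, pools microglia events and discriminates injured vs sham
#' within a hemisphere with each requested classifier. Events may be
#' downsampled per class for tractability.
#'
#' @param cohort Gated cohort.
#' @param hemisphere Hemisphere compared across groups.
#' @param classifiers Classifiers to run.
#' @param n_per_class Events per class after downsampling (`Inf` to keep
#'   all).
#' @param k,runs,seed Passed to [crossval_discriminate()].
#' @return Tibble: one row per (panel, hemisphere, classifier) with
#'   `auc_mean`, `auc_sd` and list column `result`.
#' @export
cohort_discriminate <- function(cohort, hemisphere = "ipsilateral",
                                classifiers = c("logistic", "random_forest",
                                                "rbf_svm"),
                                n_per_class = 2000, k = 10, runs = 10,
                                seed = 1L) {
  purrr::map_dfr(unique(cohort$panel), function(panel) {
    sub <- cohort[cohort$panel == panel & cohort$hemisphere == hemisphere, ]
    pool <- function(grp) {
      dplyr::bind_rows(sub$microglia[sub$group == grp])[panel_markers(panel)]
    }
    inj <- pool("CCI"); sham <- pool("sham")
    if (is.finite(n_per_class)) {
      inj <- inj[downsample_events(inj, n_per_class, seed = seed), ,
                 drop = FALSE]
      sham <- sham[downsample_events(sham, n_per_class, seed = seed + 1), ,
                   drop = FALSE]
    }
    X <- dplyr::bind_rows(inj, sham)
    y <- rep(c(TRUE, FALSE), c(nrow(inj), nrow(sham)))
    purrr::map_dfr(classifiers, function(cl) {
      res <- crossval_discriminate(X, y, classifier = cl, k = k, runs = runs,
                                   seed = seed)
      tibble::tibble(panel = panel, hemisphere = hemisphere, classifier = cl,
                     auc_mean = res$auc_mean, auc_sd = res$auc_sd,
                     result = list(res))
    })
  })
}
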