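# Risk-model construction: missingness filtering, random-forest
# imputation, development-fitted feature encoding, SMOTE, the boosted
# classifier and the surrogate-guided tuner.

make_clin_toy <- function() {
  tibble::tibble(
    patient_id = sprintf("p%02d", 1:10),
    outcome = rep(c(0L, 1L), 5),
    a = c(NA, NA, NA, NA, 5, 6, 7, 8, 9, 10),     # 40% missing -> dropped
    b = c(NA, NA, NA, 4:10),                      # 30% missing -> kept
    c = 1:10                                      # complete
  )
}

test_that("columns strictly above the missingness threshold are excluded", {
  out <- filter_missing(make_clin_toy(), max_missing = 0.3)
  expect_setequal(names(out), c("patient_id", "outcome", "b", "c"))
  expect_identical(attr(out, "dropped"), "a")
  # identifier and outcome columns are never candidates for exclusion
  all_na <- tibble::tibble(patient_id = "p", outcome = 1L, x = NA_real_)
  expect_false("x" %in% names(filter_missing(all_na)))
  expect_true(all(c("patient_id", "outcome") %in% names(filter_missing(all_na))))
})

test_that("forest imputation recovers correlated structure better than means", {
  set.seed(42)
  n <- 120
  u <- rnorm(n)
  full <- tibble::tibble(patient_id = sprintf("p%03d", 1:n),
                         outcome = rbinom(n, 1, 0.3),
                         x1 = u + rnorm(n, sd = 0.1),
                         x2 = 2 * u + rnorm(n, sd = 0.1),
                         x3 = rnorm(n))
  holes <- sample(n, 25)
  obs <- full
  obs$x2[holes] <- NA
  imp <- impute_missing(obs, seed = 3)
  expect_false(anyNA(imp$x2))
  err_forest <- mean((imp$x2[holes] - full$x2[holes])^2)
  err_mean <- mean((mean(obs$x2, na.rm = TRUE) - full$x2[holes])^2)
  expect_lt(err_forest, 0.5 * err_mean)
  # observed cells are never modified
  expect_identical(imp$x2[-holes], full$x2[-holes])
  # deterministic under the seed
  expect_identical(imp, impute_missing(obs, seed = 3))
})

test_that("categorical imputation fills with existing levels only", {
  set.seed(9)
  n <- 80
  g <- sample(c("low", "high"), n, replace = TRUE)
  tb <- tibble::tibble(patient_id = as.character(1:n), outcome = 0L,
                       g = g, x = (g == "high") * 2 + rnorm(n, sd = 0.2))
  tb$g[sample(n, 15)] <- NA
  imp <- impute_missing(tb, seed = 1)
  expect_false(anyNA(imp$g))
  expect_true(all(imp$g %in% c("low", "high")))
  expect_type(imp$g, "character")
})

test_that("an incomplete outcome column is rejected before imputation", {
  tb <- tibble::tibble(patient_id = c("a", "b"), outcome = c(1L, NA),
                       x = c(1, NA))
  expect_error(impute_missing(tb), "outcome")
})

test_that("the feature encoder applies development statistics to new rows", {
  dev <- tibble::tibble(patient_id = as.character(1:4), outcome = 0L,
                        age = c(40, 50, 60, 70),
                        sex = c("f", "m", "f", "m"))
  enc <- fit_feature_encoder(dev)
  Xd <- apply_feature_encoder(enc, dev)
  # z-scores computed from the development mean/SD
  expect_equal(Xd[, "age"], (dev$age - 55) / sd(dev$age), ignore_attr = TRUE)
  expect_setequal(colnames(Xd), c("age", "sex_f", "sex_m"))
  expect_equal(rowSums(Xd[, c("sex_f", "sex_m")]), rep(1, 4),
               ignore_attr = TRUE)
  # external rows reuse the development statistics, never re-fit
  ext <- tibble::tibble(patient_id = "x", outcome = 1L, age = 55, sex = "f")
  Xe <- apply_feature_encoder(enc, ext)
  expect_equal(Xe[, "age"], 0, ignore_attr = TRUE)
  # unseen level maps to an all-zero indicator block with a warning
  odd <- tibble::tibble(patient_id = "y", outcome = 1L, age = 55,
                        sex = "other")
  expect_warning(Xo <- apply_feature_encoder(enc, odd), "unseen")
  expect_equal(unname(Xo[, c("sex_f", "sex_m")]), c(0, 0))
  # a missing feature column is a schema error
  expect_error(apply_feature_encoder(enc, dev[-3]),
               class = "deeprisk_schema_error")
})

test_that("SMOTE balances classes with convex minority interpolations", {
  set.seed(5)
  X <- rbind(matrix(rnorm(40, mean = 0), ncol = 2),
             matrix(rnorm(10, mean = 4), ncol = 2))
  y <- c(rep(0, 20), rep(1, 5))
  sm <- smote_oversample(X, y, seed = 2)
  expect_equal(sum(sm$y == 1), sum(sm$y == 0))
  expect_equal(nrow(sm$X), length(sm$y))
  # originals are preserved at the top
  expect_identical(sm$X[1:25, ], X)
  # synthetic rows interpolate minority points, so they stay inside the
  # minority bounding box coordinate-wise
  synth <- sm$X[-(1:25), , drop = FALSE]
  Xm <- X[y == 1, ]
  for (j in 1:2) {
    expect_true(all(synth[, j] >= min(Xm[, j]) - 1e-12))
    expect_true(all(synth[, j] <= max(Xm[, j]) + 1e-12))
  }
  expect_identical(sm, smote_oversample(X, y, seed = 2))
  # already balanced data passes through untouched
  bal <- smote_oversample(X[1:10, ], rep(c(0, 1), 5), seed = 1)
  expect_identical(bal$X, X[1:10, ])
  expect_error(smote_oversample(X, c(rep(0, 24), 1)),
               class = "deeprisk_parameter_error")
})

make_sep_data <- function(n = 160, seed = 7, shift = 2) {
  set.seed(seed)
  y <- rep(c(0L, 1L), n / 2)
  X <- cbind(s1 = rnorm(n) + shift * y, s2 = rnorm(n) - shift * y,
             noise = rnorm(n))
  list(X = X, y = y)
}

test_that("the classifier separates a signal cohort but not shuffled labels", {
  d <- make_sep_data()
  tr <- 1:120; te <- 121:160
  m <- train_classifier(d$X[tr, ], d$y[tr], seed = 4)
  pr <- predict_risk(m, d$X[te, ])
  expect_gt(auroc(pr$probability, d$y[te]), 0.9)
  expect_true(all(pr$probability >= 0 & pr$probability <= 1))
  # shuffled labels give chance-level held-out discrimination
  set.seed(11)
  m0 <- train_classifier(d$X[tr, ], sample(d$y[tr]), seed = 4)
  a0 <- auroc(predict_risk(m0, d$X[te, ])$probability, d$y[te])
  expect_lt(abs(a0 - 0.5), 0.2)
})

test_that("prediction is invariant to feature column order", {
  d <- make_sep_data(n = 80)
  m <- train_classifier(d$X, d$y, seed = 1)
  p1 <- predict_risk(m, d$X)$probability
  p2 <- predict_risk(m, d$X[, c("noise", "s2", "s1")])$probability
  expect_equal(p1, p2)
  expect_error(predict_risk(m, d$X[, 1:2]), class = "deeprisk_schema_error")
  expect_error(train_classifier(d$X, rep(1L, 80)),
               class = "deeprisk_parameter_error")
})

test_that("model accessors expose the branch, features and hyperparameters", {
  d <- make_sep_data(n = 80)
  m <- train_classifier(d$X, d$y, config = list(max_depth = 2, nrounds = 40),
                        seed = 1, branch = "clinical")
  expect_output(print(m), "clinical")
  g <- glance(m)
  expect_equal(g$branch, "clinical")
  expect_equal(g$n_features, 3L)
  expect_equal(g$nrounds, 40)
  td <- tidy(m)
  expect_true(all(td$feature %in% colnames(d$X)))
  expect_gt(td$gain[td$feature == "s1"], td$gain[td$feature == "noise"])
})

test_that("the surrogate-guided tuner improves on its worst random trial", {
  d <- make_sep_data(n = 120, shift = 1)
  space <- default_search_space()
  space$nrounds <- list(lo = 20, hi = 60, integer = TRUE)
  res <- tune_hyperparameters(d$X, d$y, space = space, k_folds = 3,
                              n_trials = 6, seed = 2)
  expect_equal(nrow(res$trials), 6)
  expect_equal(res$best_auroc, max(res$trials$cv_auroc))
  expect_true(all(c("max_depth", "eta", "nrounds") %in% names(res$best)))
  expect_gte(res$best_auroc, min(res$trials$cv_auroc))
  # deterministic under the seed
  res2 <- tune_hyperparameters(d$X, d$y, space = space, k_folds = 3,
                               n_trials = 6, seed = 2)
  expect_identical(res$trials$cv_auroc, res2$trials$cv_auroc)
})

test_that("cross-validation refuses folds containing a single class", {
  set.seed(1)
  X <- matrix(rnorm(60), ncol = 2)
  y <- c(rep(0L, 27), rep(1L, 3))
  expect_error(
    tune_hyperparameters(X, y, k_folds = 5, n_trials = 2, seed = 1),
    class = "deeprisk_stratification_error")
})
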