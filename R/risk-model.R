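# Risk classifier construction: missing-data filtering and random-forest
# imputation, one-hot/z-score feature encoding fitted on the development
# cohort only, SMOTE oversampling inside training folds, surrogate-guided
# hyperparameter search, and the gradient-boosted classifier itself.

feature_cols <- function(table, exclude = c("patient_id", "outcome", "cohort")) {
  setdiff(names(table), exclude)
}

#' Drop columns with excessive missingness
#'
#' Removes feature columns whose missing fraction exceeds `max_missing`
#' (strictly above; the development rule is "over 30% missing").
#'
#' @param table A data frame / tibble.
#' @param max_missing Threshold (default 0.3).
#' @return The table without the excluded columns; the dropped names are
#'   attached as attribute `dropped`.
#' @export
filter_missing <- function(table, max_missing = 0.3) {
  fc <- feature_cols(table)
  frac <- vapply(table[fc], function(x) mean(is.na(x)), numeric(1))
  drop <- fc[frac > max_missing]
  out <- table[setdiff(names(table), drop)]
  attr(out, "dropped") <- drop
  out
}

#' Random-forest iterative imputation
#'
#' Columns above `max_missing` missing are removed first.  Remaining
#' missing cells are initialized with the column mean (continuous) or mode
#' (categorical); then, repeatedly and in order of increasing missingness,
#' each incomplete column is re-predicted from all others by a random
#' forest fit on the originally observed rows, until the successive fills
#' change less than `tol` (relative, continuous columns) or `max_iter`
#' rounds.
#'
#' @param table A tibble; the `outcome` column (if present) must be
#'   complete and is never used as an imputation predictor.
#' @param max_missing Column-exclusion threshold (default 0.3).
#' @param max_iter Maximum rounds (default 10).
#' @param tol Relative-change stopping tolerance (default 1e-3).
#' @param num_trees Trees per forest (default 100).
#' @param seed Integer seed.
#' @return The completed tibble (excluded columns absent).
#' @export
impute_missing <- function(table, max_missing = 0.3, max_iter = 10,
                           tol = 1e-3, num_trees = 100, seed = 1L) {
  if ("outcome" %in% names(table)) {
    assert_that(!anyNA(table$outcome), "outcome column must be complete")
  }
  table <- filter_missing(table, max_missing)
  dropped <- attr(table, "dropped")
  fc <- feature_cols(table)
  miss <- vapply(table[fc], anyNA, logical(1))
  if (!any(miss)) {
    attr(table, "dropped") <- dropped
    return(table)
  }
  work <- as.data.frame(table[fc])
  ischar <- vapply(work, function(x) is.character(x) || is.factor(x), logical(1))
  for (cl in names(work)[ischar]) work[[cl]] <- factor(work[[cl]])
  na_idx <- lapply(work, function(x) which(is.na(x)))
  # mean/mode initialization
  for (cl in names(work)) {
    idx <- na_idx[[cl]]
    if (!length(idx)) next
    if (is.factor(work[[cl]])) {
      mode_lv <- names(which.max(table(work[[cl]])))
      work[[cl]][idx] <- mode_lv
    } else {
      work[[cl]][idx] <- mean(work[[cl]], na.rm = TRUE)
    }
  }
  order_cols <- names(sort(vapply(na_idx, length, integer(1))))
  order_cols <- order_cols[vapply(order_cols, function(cl)
    length(na_idx[[cl]]) > 0, logical(1))]
  with_seed(seed, {
    for (iter in seq_len(max_iter)) {
      max_change <- 0
      for (cl in order_cols) {
        idx <- na_idx[[cl]]
        obs <- setdiff(seq_len(nrow(work)), idx)
        fit <- ranger::ranger(
          x = work[obs, setdiff(names(work), cl), drop = FALSE],
          y = work[[cl]][obs], num.trees = num_trees,
          seed = derive_seed(seed, paste0(cl, iter)),
          num.threads = 1, verbose = FALSE)
        pred <- predict(fit, work[idx, setdiff(names(work), cl), drop = FALSE],
                        num.threads = 1)$predictions
        old <- work[[cl]][idx]
        work[[cl]][idx] <- pred
        if (is.numeric(pred)) {
          denom <- sum(pred^2)
          ch <- if (denom > 0) sqrt(sum((pred - old)^2) / denom) else 0
        } else {
          ch <- mean(pred != old)
        }
        max_change <- max(max_change, ch)
      }
      if (max_change < tol) break
    }
  })
  for (cl in names(work)) {
    table[[cl]] <- if (is.factor(work[[cl]])) as.character(work[[cl]])
                   else work[[cl]]
  }
  attr(table, "dropped") <- dropped
  table
}

#' Fit a feature encoder on the development cohort
#'
#' Records the categorical levels and the continuous means/SDs of the
#' development rows; [apply_feature_encoder()] one-hot encodes
#' categoricals (k levels -> k indicators) and z-scores continuous columns
#' using these development statistics, so external rows are transformed
#' with the fitted encoder, never re-fit.
#'
#' @param table Imputed development table.
#' @return An object of class `feature_encoder`.
#' @export
fit_feature_encoder <- function(table) {
  fc <- feature_cols(table)
  spec <- lapply(table[fc], function(x) {
    if (is.character(x) || is.factor(x)) {
      list(type = "categorical", levels = sort(unique(as.character(x))))
    } else {
      s <- stats::sd(x)
      list(type = "continuous", mean = mean(x), sd = if (s > 0) s else 1)
    }
  })
  structure(list(spec = spec, columns = fc), class = "feature_encoder")
}

#' Apply a fitted feature encoder
#'
#' @param encoder A [fit_feature_encoder()] object.
#' @param table Table with the encoder's columns (development or external).
#' @return Numeric design matrix; unseen categorical levels map to all-zero
#'   indicator rows with a warning.
#' @export
apply_feature_encoder <- function(encoder, table) {
  stopifnot(inherits(encoder, "feature_encoder"))
  missing_cols <- setdiff(encoder$columns, names(table))
  if (length(missing_cols)) {
    abort(paste("missing feature columns:", paste(missing_cols, collapse = ", ")),
          class = "deeprisk_schema_error")
  }
  blocks <- lapply(encoder$columns, function(cl) {
    sp <- encoder$spec[[cl]]
    x <- table[[cl]]
    if (sp$type == "categorical") {
      x <- as.character(x)
      unseen <- setdiff(unique(x), sp$levels)
      if (length(unseen)) {
        warn(sprintf("unseen level(s) in %s mapped to all-zero indicators: %s",
                     cl, paste(unseen, collapse = ", ")))
      }
      m <- vapply(sp$levels, function(lv) as.numeric(x == lv),
                  numeric(length(x)))
      m <- matrix(m, nrow = length(x))
      colnames(m) <- paste(cl, sp$levels, sep = "_")
      m
    } else {
      m <- matrix((x - sp$mean) / sp$sd, ncol = 1)
      colnames(m) <- cl
      m
    }
  })
  do.call(cbind, blocks)
}

#' SMOTE oversampling
#'
#' Balances the classes by adding synthetic minority rows
#' `x + lambda * (x_nn - x)` with `lambda ~ U(0, 1)` and `x_nn` one of the
#' `k` nearest minority neighbours of `x` (Euclidean).
#'
#' @param X Numeric design matrix.
#' @param y 0/1 labels.
#' @param k Neighbour count (default 5, capped at minority size - 1).
#' @param seed Integer seed.
#' @return List with balanced `X` and `y`; synthetic rows are appended
#'   after the originals.
#' @export
smote_oversample <- function(X, y, k = 5, seed = 1L) {
  y <- as.integer(y)
  counts <- table(factor(y, levels = c(0, 1)))
  minority <- as.integer(names(which.min(counts)))
  n_min <- min(counts); n_maj <- max(counts)
  if (n_min < 2) {
    abort("minority class needs at least 2 members for SMOTE",
          class = "deeprisk_parameter_error")
  }
  n_new <- n_maj - n_min
  if (n_new == 0) return(list(X = X, y = y))
  Xm <- X[y == minority, , drop = FALSE]
  k <- min(k, nrow(Xm) - 1)
  d <- as.matrix(stats::dist(Xm))
  diag(d) <- Inf
  nn <- apply(d, 1, function(r) order(r)[seq_len(k)])
  nn <- if (k == 1) matrix(nn, ncol = 1) else t(nn)
  synth <- with_seed(seed, {
    base_i <- sample.int(nrow(Xm), n_new, replace = TRUE)
    nbr_i <- vapply(base_i, function(i) nn[i, sample.int(k, 1)], integer(1))
    lam <- runif(n_new)
    Xm[base_i, , drop = FALSE] +
      lam * (Xm[nbr_i, , drop = FALSE] - Xm[base_i, , drop = FALSE])
  })
  list(X = rbind(X, synth), y = c(y, rep(minority, n_new)))
}

#' Default gradient-boosting hyperparameter search space
#'
#' @return A list of class `search_space`: per-hyperparameter `(lo, hi)`
#'   ranges (`log = TRUE` sampled log-uniformly, `integer = TRUE` rounded).
#' @export
default_search_space <- function() {
  structure(list(
    max_depth = list(lo = 2, hi = 8, integer = TRUE),
    eta = list(lo = 0.01, hi = 0.3, log = TRUE),
    nrounds = list(lo = 50, hi = 500, integer = TRUE),
    subsample = list(lo = 0.5, hi = 1),
    min_child_weight = list(lo = 1, hi = 10),
    alpha = list(lo = 0, hi = 5),
    lambda = list(lo = 0, hi = 5)
  ), class = "search_space")
}

sample_space <- function(space, n) {
  draws <- lapply(names(space), function(nm) {
    sp <- space[[nm]]
    if (identical(sp$lo, sp$hi)) return(rep(sp$lo, n))
    x <- if (isTRUE(sp$log)) exp(runif(n, log(sp$lo), log(sp$hi)))
         else runif(n, sp$lo, sp$hi)
    if (isTRUE(sp$integer)) x <- round(x)
    x
  })
  names(draws) <- names(space)
  tibble::as_tibble(draws)
}

stratified_folds <- function(y, k, seed) {
  with_seed(seed, {
    fold <- integer(length(y))
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep(seq_len(k), length.out = length(idx))
    }
    fold
  })
}

fit_xgb <- function(X, y, config, seed = 1L, nthread = 1) {
  xgboost::xgb.train(
    params = xgboost::xgb.params(
      objective = "binary:logistic", max_depth = config$max_depth,
      eta = config$eta, subsample = config$subsample,
      min_child_weight = config$min_child_weight,
      alpha = config$alpha, lambda = config$lambda,
      nthread = nthread, seed = seed %% 2147483647),
    data = xgboost::xgb.DMatrix(X, label = y, nthread = nthread),
    nrounds = config$nrounds, verbose = 0)
}

cv_auroc <- function(X, y, config, k_folds, seed, smote = TRUE) {
  fold <- stratified_folds(y, k_folds, derive_seed(seed, "folds"))
  scores <- numeric(length(y))
  for (f in seq_len(k_folds)) {
    tr <- fold != f
    if (length(unique(y[tr])) < 2 || length(unique(y[!tr])) < 2) {
      abort("a cross-validation fold contains a single class",
            class = "deeprisk_stratification_error")
    }
    Xtr <- X[tr, , drop = FALSE]; ytr <- y[tr]
    if (smote) {
      sm <- smote_oversample(Xtr, ytr, seed = derive_seed(seed, paste0("sm", f)))
      Xtr <- sm$X; ytr <- sm$y
    }
    fit <- fit_xgb(Xtr, ytr, config, seed = derive_seed(seed, paste0("xgb", f)))
    scores[!tr] <- predict(fit, X[!tr, , drop = FALSE])
  }
  auroc(scores, y)
}

#' Surrogate-guided hyperparameter search
#'
#' Sequential model-based optimization of the stratified cross-validated
#' AUROC: after `n_init` random evaluations, a random-forest surrogate is
#' fit to the trial history and each next trial maximizes an
#' upper-confidence acquisition (predicted mean + exploration bonus from
#' the between-tree spread) over a fresh candidate pool.  SMOTE is re-fit
#' inside each training fold.  Deterministic given `seed`.
#'
#' @param X Numeric design matrix (development cohort).
#' @param y 0/1 labels.
#' @param space A [default_search_space()]-style list.
#' @param k_folds Stratified folds (default 5).
#' @param n_trials Total trials (default 50).
#' @param seed Integer seed.
#' @param smote Balance classes inside training folds (default TRUE).
#' @return List with `best` (named hyperparameter list), `best_auroc`, and
#'   `trials` (tibble of all evaluations).
#' @export
tune_hyperparameters <- function(X, y, space = default_search_space(),
                                 k_folds = 5, n_trials = 50, seed = 1L,
                                 smote = TRUE) {
  stopifnot(inherits(space, "search_space") || is.list(space))
  n_init <- max(2L, min(10L, as.integer(ceiling(n_trials / 5))))
  n_init <- min(n_init, n_trials)
  cand0 <- with_seed(derive_seed(seed, "init"), sample_space(space, n_init))
  trials <- cand0
  trials$cv_auroc <- vapply(seq_len(n_init), function(i) {
    cv_auroc(X, y, as.list(cand0[i, ]), k_folds,
             derive_seed(seed, paste0("trial", i)), smote = smote)
  }, numeric(1))
  i <- n_init
  while (i < n_trials) {
    i <- i + 1
    pool <- with_seed(derive_seed(seed, paste0("pool", i)),
                      sample_space(space, 200))
    param_cols <- names(space)
    sur <- ranger::ranger(
      x = as.data.frame(trials[param_cols]), y = trials$cv_auroc,
      num.trees = 200, seed = derive_seed(seed, paste0("sur", i)),
      num.threads = 1, verbose = FALSE)
    pred_all <- predict(sur, as.data.frame(pool), num.threads = 1,
                        predict.all = TRUE)$predictions
    mu <- rowMeans(pred_all)
    sdv <- apply(pred_all, 1, stats::sd)
    pick <- which.max(mu + sdv)
    cfg <- as.list(pool[pick, ])
    score <- cv_auroc(X, y, cfg, k_folds,
                      derive_seed(seed, paste0("trial", i)), smote = smote)
    trials <- dplyr::bind_rows(trials, dplyr::mutate(pool[pick, ],
                                                     cv_auroc = score))
  }
  best_i <- which.max(trials$cv_auroc)
  list(best = as.list(trials[best_i, names(space)]),
       best_auroc = trials$cv_auroc[best_i], trials = trials)
}

#' Train the gradient-boosted risk classifier
#'
#' Fits an XGBoost binary classifier on the (optionally SMOTE-balanced)
#' development matrix, preserving feature names for explainability.
#'
#' @param X Numeric design matrix with column names.
#' @param y 0/1 labels.
#' @param config Hyperparameter list (see [default_search_space()]); any
#'   missing entry falls back to a moderate default.
#' @param smote Balance classes before fitting (default TRUE).
#' @param seed Integer seed.
#' @param branch Branch label stored on the model
#'   (`"multimodal"`, `"mri"`, `"ecg"`, `"clinical"`).
#' @return An object of class `deeprisk_model`.
#' @export
train_classifier <- function(X, y, config = NULL, smote = TRUE, seed = 1L,
                             branch = "multimodal") {
  y <- as.integer(y)
  if (length(unique(y)) < 2) {
    abort("y must contain both classes", class = "deeprisk_parameter_error")
  }
  defaults <- list(max_depth = 4, eta = 0.1, nrounds = 150, subsample = 0.9,
                   min_child_weight = 1, alpha = 0, lambda = 1)
  config <- utils::modifyList(defaults, config %||% list())
  Xf <- X; yf <- y
  if (smote) {
    sm <- smote_oversample(X, y, seed = derive_seed(seed, "smote"))
    Xf <- sm$X; yf <- sm$y
  }
  fit <- fit_xgb(Xf, yf, config, seed = derive_seed(seed, "fit"))
  structure(list(booster = fit, feature_names = colnames(X), config = config,
                 branch = branch, seed = seed, n_train = length(y),
                 prevalence = mean(y)),
            class = "deeprisk_model")
}

#' @export
print.deeprisk_model <- function(x, ...) {
  cat(sprintf("<deeprisk_model:%s> %d features, trained on %d patients (%.1f%% events)\n",
              x$branch, length(x$feature_names), x$n_train,
              100 * x$prevalence))
  invisible(x)
}

#' Predict one-year arrhythmic risk
#'
#' @param model A [train_classifier()] fit.
#' @param X Numeric matrix with the model's feature columns.
#' @param patient_id Optional ids (defaults to row numbers).
#' @return A tibble with `patient_id`, `probability`, `branch`; row order
#'   preserved.
#' @export
predict_risk <- function(model, X, patient_id = NULL) {
  stopifnot(inherits(model, "deeprisk_model"))
  if (!is.null(colnames(X))) {
    missing_cols <- setdiff(model$feature_names, colnames(X))
    if (length(missing_cols)) {
      abort(paste("missing feature columns:",
                  paste(missing_cols, collapse = ", ")),
            class = "deeprisk_schema_error")
    }
    X <- X[, model$feature_names, drop = FALSE]
  }
  p <- predict(model$booster, X)
  tibble::tibble(patient_id = patient_id %||% seq_len(nrow(X)),
                 probability = p, branch = model$branch)
}

#' @export
tidy.deeprisk_model <- function(x, ...) {
  imp <- xgboost::xgb.importance(model = x$booster)
  tibble::tibble(feature = imp$Feature, gain = imp$Gain, cover = imp$Cover,
                 frequency = imp$Frequency)
}

#' @export
glance.deeprisk_model <- function(x, ...) {
  tibble::tibble(branch = x$branch, n_features = length(x$feature_names),
                 n_train = x$n_train, prevalence = x$prevalence,
                 nrounds = x$config$nrounds, max_depth = x$config$max_depth,
                 eta = x$config$eta)
}
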