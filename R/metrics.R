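# Discrimination, calibration and comparison statistics for binary risk
# predictions: AUROC/AUPRC, confusion-table metrics, Youden cut-points,
# percentile-bootstrap confidence intervals, DeLong's test for correlated
# AUROCs, and calibration slope.

check_binary <- function(labels) {
  assert_that(all(labels %in% c(0, 1)), "labels must be 0/1")
  if (length(unique(labels)) < 2) {
    abort("both classes must be present", class = "deeprisk_undefined_metric")
  }
}

#' Area under the ROC curve
#'
#' Pair-counting (Mann-Whitney) estimator: the fraction of
#' positive-negative pairs ranked concordantly, with ties counted half.
#'
#' @param scores Numeric risk scores (higher = more positive).
#' @param labels 0/1 outcome labels.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  check_binary(labels)
  r <- rank(scores, ties.method = "average")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# ROC curve points (fpr, tpr) over all unique-score thresholds, for
# trapezoidal integration and plotting.
roc_curve <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  n1 <- sum(y); n0 <- length(y) - n1
  tp <- cumsum(y); fp <- cumsum(1 - y)
  keep <- c(s[-1] != s[-length(s)], TRUE)
  tibble::tibble(threshold = c(Inf, s[keep]),
                 tpr = c(0, tp[keep] / n1),
                 fpr = c(0, fp[keep] / n0))
}

# Trapezoidal AUROC from the curve; agrees with the pair-counting
# estimator (ties handled by the diagonal segment).
auroc_trapezoid <- function(scores, labels) {
  rc <- roc_curve(scores, labels)
  sum(diff(rc$fpr) * (head(rc$tpr, -1) + tail(rc$tpr, -1)) / 2)
}

#' Area under the precision-recall curve
#'
#' Average-precision convention: the step-wise sum of precision at each
#' recall increment, descending the score ranking (ties processed as one
#' block).
#'
#' @inheritParams auroc
#' @return AUPRC in `(0, 1]`.
#' @export
auprc <- function(scores, labels) {
  assert_that(all(labels %in% c(0, 1)), "labels must be 0/1")
  if (sum(labels == 1) == 0) {
    abort("no positive labels: AUPRC undefined", class = "deeprisk_undefined_metric")
  }
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]; s <- scores[ord]
  tp <- cumsum(y); fp <- cumsum(1 - y)
  n1 <- sum(y)
  keep <- c(s[-1] != s[-length(s)], TRUE)
  tp <- tp[keep]; fp <- fp[keep]
  prec <- tp / (tp + fp)
  rec <- tp / n1
  sum(diff(c(0, rec)) * prec)
}

#' Confusion-table metrics at a threshold
#'
#' Predicted positive means `score >= threshold` (ties at the threshold
#' count as positive).  When no patient is predicted positive, PPV (and
#' F1) are reported as `NA` rather than 0.
#'
#' @inheritParams auroc
#' @param threshold Decision threshold.
#' @return A tibble with `sensitivity`, `specificity`, `ppv`, `npv`,
#'   `accuracy`, `f1` plus the table counts `tp`, `fp`, `tn`, `fn`.
#' @export
threshold_metrics <- function(scores, labels, threshold) {
  check_binary(labels)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1); fp <- sum(pred == 1 & labels == 0)
  tn <- sum(pred == 0 & labels == 0); fn <- sum(pred == 0 & labels == 1)
  ppv <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  npv <- if (tn + fn == 0) NA_real_ else tn / (tn + fn)
  sens <- tp / (tp + fn)
  f1 <- if (is.na(ppv) || ppv + sens == 0) NA_real_ else
    2 * ppv * sens / (ppv + sens)
  tibble::tibble(sensitivity = sens, specificity = tn / (tn + fp),
                 ppv = ppv, npv = npv,
                 accuracy = (tp + tn) / length(labels), f1 = f1,
                 tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Youden-optimal cut-point
#'
#' Exhaustive scan over midpoints between adjacent unique scores (plus
#' outer sentinels), maximizing `J = sensitivity + specificity - 1`.
#' Ties in J are broken toward the higher-specificity (higher-threshold)
#' cut-point.
#'
#' @inheritParams auroc
#' @return A list of class `cutpoint_result` with `threshold` and `J`.
#' @export
youden_cutpoint <- function(scores, labels) {
  check_binary(labels)
  u <- sort(unique(scores))
  cand <- c(min(u) - 1, (head(u, -1) + tail(u, -1)) / 2, max(u) + 1)
  js <- vapply(cand, function(th) {
    m <- threshold_metrics(scores, labels, th)
    m$sensitivity + m$specificity - 1
  }, numeric(1))
  best_j <- max(js)
  # among maximal J, take the largest threshold (higher specificity)
  th <- max(cand[js >= best_j - 1e-12])
  structure(list(threshold = th, J = best_j), class = "cutpoint_result")
}

#' Percentile bootstrap confidence interval for a metric
#'
#' Resamples patients with replacement, recomputes `metric_fn` per
#' replicate, and reports the 2.5/97.5 percentile interval.  Replicates
#' with a single class are skipped and counted; more than 50% degenerate
#' replicates raise an error.
#'
#' @inheritParams auroc
#' @param metric_fn Function `(scores, labels) -> numeric(1)`.
#' @param n_iter Bootstrap iterations (3000 in the reference analysis
#'   protocol).
#' @param seed Integer seed.
#' @param conf Confidence level (default 0.95).
#' @return A tibble with `point`, `lo`, `hi`, `n_iter`, `n_degenerate`.
#' @export
bootstrap_ci <- function(scores, labels, metric_fn, n_iter = 3000, seed = 1L,
                         conf = 0.95) {
  assert_that(length(scores) >= 10, "need at least 10 observations")
  point <- metric_fn(scores, labels)
  n <- length(scores)
  reps <- with_seed(seed, {
    vapply(seq_len(n_iter), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(labels[idx])) < 2) return(NA_real_)
      metric_fn(scores[idx], labels[idx])
    }, numeric(1))
  })
  n_deg <- sum(is.na(reps))
  if (n_deg > n_iter / 2) {
    abort(sprintf("unstable CI: %d of %d replicates degenerate", n_deg, n_iter),
          class = "deeprisk_unstable_ci")
  }
  alpha <- (1 - conf) / 2
  q <- quantile(reps, c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE,
                type = 7)
  tibble::tibble(point = point, lo = q[1], hi = q[2], n_iter = n_iter,
                 n_degenerate = n_deg)
}

#' DeLong's test for two correlated AUROCs
#'
#' Placement-value (structural component) formulation: `V10` per positive
#' and `V01` per negative give the covariance matrix of the paired AUROC
#' estimates; `z = dAUC / sqrt(var(dAUC))` with a two-sided normal
#' p-value.  Identical score vectors (zero variance of the difference)
#' return a degenerate flag with `p = 1`.
#'
#' @param scores_a,scores_b Paired score vectors on the same patients.
#' @param labels 0/1 outcome labels.
#' @return A tibble with `auc_a`, `auc_b`, `delta_auc`, `z`, `p`,
#'   `degenerate`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  check_binary(labels)
  assert_that(length(scores_a) == length(scores_b) &&
                length(scores_a) == length(labels),
              "scores_a, scores_b and labels must be the same length")
  placements <- function(s) {
    xs <- s[labels == 1]; ys <- s[labels == 0]
    v10 <- vapply(xs, function(x)
      mean((x > ys) + 0.5 * (x == ys)), numeric(1))
    v01 <- vapply(ys, function(y)
      mean((xs > y) + 0.5 * (xs == y)), numeric(1))
    list(auc = mean(v10), v10 = v10, v01 = v01)
  }
  pa <- placements(scores_a)
  pb <- placements(scores_b)
  m <- length(pa$v10); n <- length(pa$v01)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  S <- s10 / m + s01 / n
  var_delta <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  delta <- pa$auc - pb$auc
  if (var_delta <= 1e-15) {
    return(tibble::tibble(auc_a = pa$auc, auc_b = pb$auc, delta_auc = delta,
                          z = 0, p = 1, degenerate = TRUE))
  }
  z <- delta / sqrt(var_delta)
  tibble::tibble(auc_a = pa$auc, auc_b = pb$auc, delta_auc = delta, z = z,
                 p = 2 * pnorm(-abs(z)), degenerate = FALSE)
}

#' Calibration curve and slope
#'
#' Bins predicted probabilities into `n_bins` equal-width bins on
#' `[0, 1]` and reports observed vs mean predicted event rates per
#' non-empty bin.  The calibration slope is the coefficient of a logistic
#' recalibration fit of the labels on `logit(score)` (scores clipped away
#' from 0/1); a straight-line fit to the binned points is also reported.
#'
#' @inheritParams auroc
#' @param n_bins Number of bins (default 10).
#' @return A list of class `calibration_result` with `bins` (tibble:
#'   `bin`, `n`, `mean_predicted`, `observed`), `slope` (logistic) and
#'   `slope_binned`.
#' @export
calibration <- function(scores, labels, n_bins = 10) {
  assert_that(all(scores >= 0 & scores <= 1),
              "scores must be probabilities in [0, 1]")
  assert_that(length(scores) >= n_bins, "need at least n_bins observations")
  edges <- seq(0, 1, length.out = n_bins + 1)
  bin <- pmin(n_bins, pmax(1, findInterval(scores, edges, rightmost.closed = TRUE)))
  bins <- tibble::tibble(score = scores, label = labels, bin = bin) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_predicted = mean(.data$score),
                     observed = mean(.data$label), .groups = "drop")
  eps <- 1e-6
  lg <- qlogis(pmin(1 - eps, pmax(eps, scores)))
  slope <- if (stats::sd(lg) < 1e-12) NA_real_ else
    unname(coef(suppressWarnings(glm(labels ~ lg, family = binomial())))[2])
  slope_binned <- if (nrow(bins) >= 2) {
    unname(coef(stats::lm(observed ~ mean_predicted, data = bins,
                          weights = bins$n))[2])
  } else NA_real_
  structure(list(bins = bins, slope = slope, slope_binned = slope_binned,
                 edges = edges, n = length(scores)),
            class = "calibration_result")
}

#' Evaluate a set of risk predictions
#'
#' Computes AUROC, AUPRC and the Youden-cut-point confusion metrics with
#' percentile-bootstrap confidence intervals.
#'
#' @param preds A tibble with columns `score`, `label` and optionally
#'   `branch` (evaluated per branch).
#' @param n_boot Bootstrap iterations (default 3000).
#' @param seed Integer seed.
#' @param threshold Decision threshold; `NULL` (default) uses the Youden
#'   cut-point per branch.
#' @return A tibble of class `metrics_report`: one row per branch and
#'   metric with `point`, `lo`, `hi`.
#' @export
evaluate_predictions <- function(preds, n_boot = 3000, seed = 1L,
                                 threshold = NULL) {
  assert_that(all(c("score", "label") %in% names(preds)),
              "preds needs columns score and label")
  if (!"branch" %in% names(preds)) preds$branch <- "model"
  out <- lapply(unique(preds$branch), function(br) {
    d <- preds[preds$branch == br, ]
    th <- threshold %||% youden_cutpoint(d$score, d$label)$threshold
    metric_fns <- list(
      auroc = auroc,
      auprc = auprc,
      sensitivity = function(s, y) threshold_metrics(s, y, th)$sensitivity,
      specificity = function(s, y) threshold_metrics(s, y, th)$specificity,
      ppv = function(s, y) threshold_metrics(s, y, th)$ppv,
      npv = function(s, y) threshold_metrics(s, y, th)$npv,
      accuracy = function(s, y) threshold_metrics(s, y, th)$accuracy,
      f1 = function(s, y) threshold_metrics(s, y, th)$f1
    )
    purrr::imap_dfr(metric_fns, function(fn, nm) {
      ci <- bootstrap_ci(d$score, d$label, fn, n_iter = n_boot,
                         seed = derive_seed(seed, paste0(br, nm)))
      tibble::tibble(branch = br, metric = nm, point = ci$point,
                     lo = ci$lo, hi = ci$hi, threshold = th)
    })
  })
  structure(dplyr::bind_rows(out), class = c("metrics_report", "tbl_df",
                                             "tbl", "data.frame"))
}

#' @export
tidy.calibration_result <- function(x, ...) x$bins

#' @export
glance.calibration_result <- function(x, ...) {
  tibble::tibble(slope = x$slope, slope_binned = x$slope_binned, n = x$n)
}

#' Plot an ROC curve
#'
#' @param preds Tibble with `score`, `label`, optional `branch`.
#' @return A ggplot.
#' @export
plot_roc <- function(preds) {
  if (!"branch" %in% names(preds)) preds$branch <- "model"
  df <- preds |>
    dplyr::group_by(.data$branch) |>
    dplyr::group_modify(~roc_curve(.x$score, .x$label)) |>
    dplyr::ungroup()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                   colour = .data$branch)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity")
}

#' Plot a calibration curve
#'
#' @param x A `calibration_result`.
#' @return A ggplot of observed vs predicted event rate per bin.
#' @export
plot_calibration <- function(x) {
  stopifnot(inherits(x, "calibration_result"))
  ggplot2::ggplot(x$bins, ggplot2::aes(x = .data$mean_predicted,
                                       y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(size = .data$n)) +
    ggplot2::geom_line() +
    ggplot2::coord_equal(xlim = 0:1, ylim = 0:1) +
    ggplot2::labs(x = "mean predicted probability", y = "observed event rate")
}
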