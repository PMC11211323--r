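# Discrimination, threshold and calibration metrics against literal
# independent oracles (pair counting, hand confusion tables, pROC).

test_that("auroc equals the pair-counting estimator on fuzzed data", {
  set.seed(101)
  for (i in 1:50) {
    n <- sample(20:120, 1)
    scores <- if (i %% 3 == 0) sample(seq(0, 1, 0.1), n, TRUE) else runif(n)
    labels <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (length(unique(labels)) < 2) next
    expect_equal(auroc(scores, labels),
                 oracle_auroc_paircount(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("auroc matches pROC and the trapezoidal ROC integral", {
  set.seed(7)
  scores <- runif(300)
  labels <- rbinom(300, 1, plogis(4 * scores - 2))
  expect_equal(auroc(scores, labels),
               as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE))),
               tolerance = 1e-12)
  expect_equal(auroc(scores, labels), auroc_trapezoid(scores, labels),
               tolerance = 1e-12)
})

test_that("perfect, inverted and constant scores give 1, 0 and 1/2", {
  y <- c(0, 0, 1, 1)
  expect_equal(auroc(c(1, 2, 3, 4), y), 1)
  expect_equal(auroc(c(4, 3, 2, 1), y), 0)
  expect_equal(auroc(c(1, 1, 1, 1), y), 0.5)
})

test_that("single-class labels raise the undefined-metric error", {
  expect_error(auroc(runif(10), rep(1, 10)),
               class = "deeprisk_undefined_metric")
  expect_error(auroc(runif(10), rep(0, 10)),
               class = "deeprisk_undefined_metric")
})

test_that("auprc matches the average-precision formula and base rate", {
  set.seed(11)
  scores <- runif(500)  # continuous, no ties
  labels <- rbinom(500, 1, 0.3)
  ap <- function(s, y) {
    o <- order(-s)
    yy <- y[o]
    prec <- cumsum(yy) / seq_along(yy)
    sum(prec * yy) / sum(yy)
  }
  expect_equal(auprc(scores, labels), ap(scores, labels), tolerance = 1e-12)
  # random scores: AP concentrates near prevalence
  expect_lt(abs(auprc(scores, labels) - mean(labels)), 0.1)
  # perfect ranking gives 1
  expect_equal(auprc(labels + runif(500) * 0.1, labels), 1)
})

test_that("threshold metrics reproduce a hand-tallied confusion table", {
  scores <- c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4, 0.3, 0.2)
  labels <- c(1, 1, 0, 1, 0, 0, 1, 0)
  # threshold 0.55, score >= threshold positive:
  # predicted positive: 0.9(1) 0.8(1) 0.7(0) 0.6(1) -> tp=3 fp=1
  # predicted negative: 0.5(0) 0.4(0) 0.3(1) 0.2(0) -> tn=3 fn=1
  m <- threshold_metrics(scores, labels, 0.55)
  expect_equal(m$tp, 3); expect_equal(m$fp, 1)
  expect_equal(m$tn, 3); expect_equal(m$fn, 1)
  expect_equal(m$sensitivity, 3 / 4)
  expect_equal(m$specificity, 3 / 4)
  expect_equal(m$ppv, 3 / 4)
  expect_equal(m$npv, 3 / 4)
  expect_equal(m$accuracy, 6 / 8)
  expect_equal(m$f1, 2 * (3 / 4) * (3 / 4) / (3 / 4 + 3 / 4))
})

test_that("threshold metrics agree with the literal oracle on fuzzed data", {
  set.seed(21)
  for (i in 1:20) {
    n <- sample(30:100, 1)
    scores <- round(runif(n), 2)
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    th <- runif(1)
    m <- threshold_metrics(scores, labels, th)
    o <- oracle_confusion(scores, labels, th)
    expect_equal(m$tp, o$tp)
    expect_equal(m$sensitivity, o$sensitivity)
    expect_equal(m$specificity, o$specificity)
    expect_equal(m$accuracy, o$accuracy)
  }
})

test_that("degenerate prediction sets yield NA ppv/f1, not division errors", {
  scores <- c(0.1, 0.2, 0.3, 0.4)
  labels <- c(0, 1, 0, 1)
  m <- threshold_metrics(scores, labels, 0.9)  # nothing predicted positive
  expect_true(is.na(m$ppv))
  expect_true(is.na(m$f1))
  expect_equal(m$specificity, 1)
  expect_equal(m$sensitivity, 0)
})

test_that("youden cut-point matches an exhaustive threshold scan", {
  set.seed(31)
  for (i in 1:10) {
    scores <- round(runif(80), 2)
    labels <- rbinom(80, 1, 0.35)
    if (length(unique(labels)) < 2) next
    yc <- youden_cutpoint(scores, labels)
    js <- vapply(sort(unique(scores)), function(th) {
      o <- oracle_confusion(scores, labels, th)
      o$sensitivity + o$specificity - 1
    }, numeric(1))
    expect_equal(yc$J, max(js), tolerance = 1e-12)
  }
})

test_that("youden ties resolve to the higher-specificity threshold", {
  # two thresholds achieve the same J; the larger must win
  scores <- c(0.1, 0.2, 0.3, 0.8, 0.9)
  labels <- c(0, 0, 0, 1, 1)
  yc <- youden_cutpoint(scores, labels)
  m <- threshold_metrics(scores, labels, yc$threshold)
  expect_equal(m$sensitivity + m$specificity - 1, 1)
  expect_gt(yc$threshold, 0.3)
})

test_that("bootstrap interval brackets the point estimate and shrinks with n", {
  set.seed(41)
  mk <- function(n) {
    s <- runif(n)
    y <- rbinom(n, 1, plogis(3 * s - 1.5))
    bootstrap_ci(s, y, auroc, n_iter = 300, seed = 5)
  }
  small <- mk(60)
  big <- mk(600)
  expect_true(small$lo <= small$point && small$point <= small$hi)
  expect_true(big$lo <= big$point && big$point <= big$hi)
  expect_lt(big$hi - big$lo, small$hi - small$lo)
})

test_that("bootstrap is deterministic under a fixed seed", {
  set.seed(43)
  s <- runif(50); y <- rbinom(50, 1, 0.4)
  a <- bootstrap_ci(s, y, auroc, n_iter = 100, seed = 9)
  b <- bootstrap_ci(s, y, auroc, n_iter = 100, seed = 9)
  expect_identical(a, b)
})

test_that("bootstrap refuses tiny samples and counts degenerate draws", {
  expect_error(bootstrap_ci(runif(5), c(0, 1, 0, 1, 0), auroc),
               class = "deeprisk_parameter_error")
  # one positive in 12: a replicate loses the positive class with
  # probability (11/12)^12 ~ 0.35, so roughly a third must be skipped
  s <- runif(12)
  y <- c(1, rep(0, 11))
  ci <- bootstrap_ci(s, y, auroc, n_iter = 400, seed = 2)
  expect_gt(ci$n_degenerate, 0.2 * 400)
  expect_lt(ci$n_degenerate, 0.5 * 400)
  expect_true(is.finite(ci$lo) && is.finite(ci$hi))
})

test_that("delong test agrees with pROC on correlated scores", {
  set.seed(51)
  n <- 250
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(x))
  sa <- x + rnorm(n, 0, 0.5)
  sb <- x + rnorm(n, 0, 1.5)
  dl <- delong_test(sa, sb, y)
  pr <- pROC::roc.test(pROC::roc(y, sa, quiet = TRUE),
                       pROC::roc(y, sb, quiet = TRUE), method = "delong")
  expect_equal(dl$p, pr$p.value, tolerance = 1e-10)
  expect_equal(dl$auc_a, as.numeric(pr$roc1$auc), tolerance = 1e-12)
  expect_equal(dl$auc_b, as.numeric(pr$roc2$auc), tolerance = 1e-12)
})

test_that("delong on identical scores degenerates to p = 1", {
  set.seed(53)
  s <- runif(60); y <- rbinom(60, 1, 0.5)
  dl <- delong_test(s, s, y)
  expect_true(dl$degenerate)
  expect_equal(dl$p, 1)
  expect_equal(dl$delta_auc, 0)
})

test_that("calibration slope recovers 1 for well-calibrated probabilities", {
  set.seed(61)
  p <- plogis(rnorm(4000))
  y <- rbinom(4000, 1, p)
  cal <- calibration(p, y)
  expect_lt(abs(cal$slope - 1), 0.15)
  # overconfident scores (logits doubled) give slope near 0.5
  p2 <- plogis(2 * qlogis(p))
  cal2 <- calibration(p2, y)
  expect_lt(abs(cal2$slope - 0.5), 0.12)
})

test_that("calibration bins partition the sample and tidy returns them", {
  set.seed(63)
  p <- runif(200); y <- rbinom(200, 1, p)
  cal <- calibration(p, y, n_bins = 10)
  expect_equal(sum(cal$bins$n), 200)
  expect_s3_class(tidy(cal), "tbl_df")
  expect_true(all(cal$bins$observed >= 0 & cal$bins$observed <= 1))
  expect_error(calibration(c(-0.1, 0.5), c(0, 1)),
               class = "deeprisk_parameter_error")
})

test_that("evaluate_predictions reports every branch at its own cut-point", {
  set.seed(71)
  n <- 120
  x <- rnorm(n); y <- rbinom(n, 1, plogis(1.5 * x))
  preds <- tibble::tibble(
    score = c(plogis(x), runif(n)),
    label = rep(y, 2),
    branch = rep(c("signal", "noise"), each = n))
  rep_ <- evaluate_predictions(preds, n_boot = 100, seed = 3)
  expect_setequal(unique(rep_$branch), c("signal", "noise"))
  expect_setequal(unique(rep_$metric),
                  c("auroc", "auprc", "sensitivity", "specificity",
                    "ppv", "npv", "accuracy", "f1"))
  au <- rep_[rep_$metric == "auroc", ]
  expect_gt(au$point[au$branch == "signal"], au$point[au$branch == "noise"])
  expect_true(all(rep_$lo <= rep_$point & rep_$point <= rep_$hi, na.rm = TRUE))
})
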