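# Explainability: Shapley attribution identities, latent rankings,
# traversal reconstructions and gradient attention maps.

make_latent_model <- function(n = 140, seed = 8) {
  set.seed(seed)
  X <- matrix(rnorm(n * 6), n)
  colnames(X) <- c(sprintf("mri_%03d", 0:2), sprintf("ecg_%03d", 0:1), "age")
  y <- as.integer(X[, "mri_000"] + 0.7 * X[, "ecg_000"] +
                    rnorm(n, sd = 0.5) > 0)
  list(X = X, y = y,
       model = train_classifier(X, y, config = list(nrounds = 60), seed = 2))
}

test_that("attributions satisfy local accuracy on every explained row", {
  d <- make_latent_model()
  att <- shapley_attributions(d$model, d$X[1:100, ])
  margin <- predict(d$model$booster, d$X[1:100, ], outputmargin = TRUE)
  # sum(phi) + base reproduces the model margin, row by row
  expect_equal(rowSums(att$phi) + att$base_value, margin,
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(att$margin, margin, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(dim(att$phi), c(100L, 6L))
  expect_identical(att$feature_names, colnames(d$X))
  # the signal feature carries more attribution mass than pure noise
  mean_abs <- colMeans(abs(att$phi))
  expect_gt(mean_abs["mri_000"], mean_abs["age"])
})

test_that("tree attributions match exact coalition enumeration on a toy", {
  set.seed(3)
  n <- 200
  X <- matrix(rnorm(n * 3), n)
  colnames(X) <- c("f1", "f2", "f3")
  y <- as.integer(X[, 1] + 0.6 * X[, 2] - 0.4 * X[, 3] +
                    rnorm(n, sd = 0.3) > 0)
  # depth-1 trees: each tree conditions on a single feature, the regime in
  # which the path-dependent explainer solves the tree-traversal game
  # exactly, so brute-force enumeration over all 2^3 coalitions must agree
  m <- train_classifier(X, y, smote = FALSE, seed = 1,
                        config = list(max_depth = 1, eta = 0.3, nrounds = 25,
                                      subsample = 1, lambda = 1))
  att <- shapley_attributions(m, X[1:5, , drop = FALSE])
  for (i in 1:5) {
    oracle <- oracle_shapley_tree(m$booster, X[i, ], p = 3)
    expect_equal(unname(att$phi[i, ]), oracle$phi, tolerance = 1e-4)
    expect_equal(att$base_value, oracle$base_value, tolerance = 1e-4)
  }
})

test_that("attribution accessors expose a tidy long table", {
  d <- make_latent_model(n = 60)
  att <- shapley_attributions(d$model, d$X[1:4, ])
  expect_output(print(att), "4 rows x 6 features")
  td <- tidy(att)
  expect_equal(nrow(td), 24)
  expect_setequal(unique(td$feature), colnames(d$X))
  expect_equal(td$phi[td$row == 2], unname(att$phi[2, ]))
  expect_error(shapley_attributions(d$model, d$X[, 1:3]),
               class = "deeprisk_schema_error")
})

test_that("latent ranking orders by absolute attribution with stable ties", {
  phi <- rbind(c(0.5, -2, 0.1, 3),
               c(1, 1, -1, 0))  # |ties| broken toward the lower index
  colnames(phi) <- c("mri_000", "mri_001", "ecg_000", "age")
  tl <- top_latents(phi, m = 3)
  expect_equal(tl[1, ], c("mri_001", "mri_000", "ecg_000"))
  expect_equal(tl[2, ], c("mri_000", "mri_001", "ecg_000"))
  # non-latent columns (age) are never ranked
  expect_false("age" %in% tl)
  # m is capped at the number of latent columns
  expect_equal(ncol(top_latents(phi, m = 10)), 3)
  idx <- attr(tl, "indices")
  expect_equal(colnames(phi)[idx[1, ]], tl[1, ])
  expect_error(top_latents(phi[, "age", drop = FALSE]), "latent")
})

make_trained_ecg_vae <- function(n = 8, epochs = 6) {
  beats <- lapply(seq_len(n), function(i)
    prep_ecg(simulate_ecg(ecg_sim_params(seed = 300 + i,
                                         heart_rate_bpm = 58 + 3 * i))))
  cfg <- vae_config("ecg", latent_dim = 4, hidden = 16, n_res = 1,
                    epochs = epochs, batch_size = 4, seed = 5)
  list(model = train_vae(beats, cfg), beats = beats)
}

test_that("a zero-offset traversal reproduces the plain decoding", {
  tv <- make_trained_ecg_vae()
  Z <- encode_cohort(tv$model, tv$beats, prefix = "ecg")
  tr <- latent_traversal(tv$model, Z, latent_index = 2, offsets = c(-1, 0, 1))
  expect_s3_class(tr, "traversal_set")
  expect_length(tr$reconstructions, 3)
  Zm <- as.matrix(Z)
  expect_equal(tr$reconstructions[[2]], vae_decode(tv$model, colMeans(Zm)))
  expect_equal(tr$sd, sd(Zm[, 2]), ignore_attr = TRUE)
  # a patient-row base traverses around that patient's latent
  tr1 <- latent_traversal(tv$model, Z, latent_index = 1, offsets = 0, base = 3)
  expect_equal(tr1$reconstructions[[1]], vae_decode(tv$model, Zm[3, ]))
  expect_error(latent_traversal(tv$model, Z, latent_index = 9),
               class = "deeprisk_parameter_error")
})

test_that("a nonzero traversal moves the output along the decoder direction", {
  tv <- make_trained_ecg_vae()
  Z <- encode_cohort(tv$model, tv$beats, prefix = "ecg")
  tr <- latent_traversal(tv$model, Z, latent_index = 1, offsets = -2:2)
  base <- tr$reconstructions[[3]]
  dists <- vapply(tr$reconstructions, function(r) sqrt(mean((r - base)^2)),
                  numeric(1))
  # distance from the base reconstruction grows with |offset|
  expect_true(all(diff(dists[1:3]) < 0))
  expect_true(all(diff(dists[3:5]) > 0))
  expect_s3_class(ggplot2::autoplot(tr), "ggplot")
})

test_that("attention on a linear encoder equals the analytic weight average", {
  cfg <- vae_config("ecg", latent_dim = 3, hidden = 0, activation = "linear",
                    seed = 4)
  model <- deeprisk:::vae_init(cfg)
  beat <- prep_ecg(simulate_ecg(ecg_sim_params(seed = 1)))
  amap <- gradient_attention_map(model, beat, latent_indices = 1:3)
  W <- model$params$enc.W_mu
  analytic <- colMeans(abs(W))
  analytic <- array(analytic / max(analytic), dim = c(12, 150))
  expect_equal(amap$map, analytic, tolerance = 1e-10)
  # subsetting the latents changes the average accordingly
  amap1 <- gradient_attention_map(model, beat, latent_indices = 2)
  an1 <- abs(W[2, ]); an1 <- array(an1 / max(an1), dim = c(12, 150))
  expect_equal(amap1$map, an1, tolerance = 1e-10)
  expect_error(gradient_attention_map(model, beat, latent_indices = 99),
               "out of range")
})

test_that("volumetric attention restricts to the scan channel and unpools", {
  cfg <- vae_config("mri", latent_dim = 2, hidden = 0, activation = "linear",
                    seed = 6)
  model <- deeprisk:::vae_init(cfg)
  vol <- prep_mri(simulate_lge_volume(mri_sim_params(seed = 2)))
  amap <- gradient_attention_map(model, vol, latent_indices = 1:2)
  expect_equal(dim(amap$map), c(12, 64, 64))
  expect_equal(max(amap$map), 1)
  # analytic: |W_mu| averaged over latents, spread uniformly across each
  # pooled block by the average-pooling stem, scan channel only
  g <- colMeans(abs(as.matrix(model$params$enc.W_mu %*% Matrix::t(model$stem))))
  arr <- array(g, dim = cfg$input_shape)[, , , 1]
  expect_equal(amap$map, arr / max(arr), tolerance = 1e-10)
})

test_that("attention overlays render for both modalities", {
  tv <- make_trained_ecg_vae(n = 6, epochs = 3)
  amap <- gradient_attention_map(tv$model, tv$beats[[1]], latent_indices = 1:2)
  expect_s3_class(plot_attention_overlay(amap, tv$beats[[1]]), "ggplot")
  cfgm <- vae_config("mri", latent_dim = 2, hidden = 0, activation = "linear",
                     seed = 6)
  mm <- deeprisk:::vae_init(cfgm)
  vol <- prep_mri(simulate_lge_volume(mri_sim_params(seed = 2)))
  am <- gradient_attention_map(mm, vol, latent_indices = 1)
  expect_s3_class(plot_attention_overlay(am, vol), "ggplot")
})
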