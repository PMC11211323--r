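# Residual beta-VAE: ELBO bookkeeping, gradient correctness, training
# determinism and latent extraction.

make_small_beats <- function(n = 6, seed0 = 100) {
  lapply(seq_len(n), function(i)
    prep_ecg(simulate_ecg(ecg_sim_params(seed = seed0 + i,
                                         heart_rate_bpm = 55 + 4 * i))))
}

test_that("configuration encodes the two modality contracts", {
  ce <- vae_config("ecg")
  cm <- vae_config("mri")
  expect_equal(ce$input_shape, c(12L, 150L))
  expect_equal(cm$input_shape, c(12L, 64L, 64L, 2L))
  expect_equal(ce$latent_dim, 32L)   # mean-beat default
  expect_equal(cm$latent_dim, 256L)  # volumetric default
  expect_error(vae_config("ecg", beta = -1),
               class = "deeprisk_parameter_error")
  expect_error(vae_config("ecg", latent_dim = 0),
               class = "deeprisk_parameter_error")
})

test_that("closed-form KL matches the analytic special cases", {
  # KL(N(0,1) || N(0,1)) = 0
  z <- matrix(0, 1, 1)
  l0 <- elbo_loss(matrix(0, 1, 4), matrix(0, 1, 4), z, z, beta = 1)
  expect_equal(l0$kl, 0)
  # KL at mu = 1, sigma = 1 equals 0.5
  l1 <- elbo_loss(matrix(0, 1, 4), matrix(0, 1, 4),
                  matrix(1, 1, 1), matrix(0, 1, 1), beta = 1)
  expect_equal(l1$kl, 0.5)
})

test_that("closed-form KL matches a Monte-Carlo estimate within 1%", {
  mu <- c(0.8, -0.5, 1.2)
  logvar <- c(0.4, -0.6, 0.1)
  kl_closed <- elbo_loss(matrix(0, 1, 2), matrix(0, 1, 2),
                         matrix(mu, 1), matrix(logvar, 1), beta = 1)$kl
  kl_mc <- oracle_kl_mc(mu, logvar, n_draws = 1e5, seed = 5)
  expect_lt(abs(kl_closed - kl_mc) / kl_closed, 0.01)
})

test_that("beta = 0 reduces the total loss to the reconstruction term", {
  set.seed(7)
  x <- matrix(rnorm(20), 2)
  xhat <- matrix(rnorm(20), 2)
  mu <- matrix(rnorm(6), 2); lv <- matrix(rnorm(6), 2)
  l <- elbo_loss(x, xhat, mu, lv, beta = 0)
  expect_equal(l$total, l$recon_loss)
  expect_equal(l$recon_loss, mean((x - xhat)^2))
  # and total = recon + beta * kl holds exactly for beta > 0
  l2 <- elbo_loss(x, xhat, mu, lv, beta = 0.37)
  expect_equal(l2$total, l2$recon_loss + 0.37 * l2$kl)
})

test_that("backpropagated gradients match central differences", {
  set.seed(3)
  cfg <- vae_config("ecg", latent_dim = 3, hidden = 6, n_res = 1,
                    beta = 0.4, seed = 2)
  model <- deeprisk:::vae_init(cfg)
  X <- matrix(rnorm(2 * cfg$input_dim, sd = 0.5), 2)
  eps <- matrix(rnorm(6), 2)
  bw <- deeprisk:::vae_backward(model, X, eps)
  loss_at <- function(nm, idx, delta) {
    m2 <- model
    m2$params[[nm]][idx] <- m2$params[[nm]][idx] + delta
    ef <- deeprisk:::enc_forward(m2, X)
    Z <- ef$mu + exp(ef$logvar / 2) * eps
    xh <- deeprisk:::dec_forward(m2, Z)$Xhat
    elbo_loss(X, xh, ef$mu, ef$logvar, cfg$beta)$total
  }
  h <- 1e-6
  for (nm in c("enc.W_in", "enc.W_mu", "enc.b_lv", "enc.res1.Wa",
               "dec.V_in", "dec.res1.Wb", "dec.V_out", "dec.c_out")) {
    idx <- if (is.matrix(model$params[[nm]])) cbind(1, 1) else 1
    num <- (loss_at(nm, idx, h) - loss_at(nm, idx, -h)) / (2 * h)
    expect_equal(bw$grads[[nm]][idx], num, tolerance = 1e-4)
  }
})

test_that("pooled-space training loss equals the full-space ELBO", {
  set.seed(5)
  cfg <- vae_config("mri", latent_dim = 4, hidden = 8, n_res = 1,
                    beta = 0.3, seed = 9)
  model <- deeprisk:::vae_init(cfg)
  V <- lapply(1:3, function(i)
    prep_mri(simulate_lge_volume(mri_sim_params(seed = i))))
  X <- deeprisk:::as_vae_matrix(V, cfg)
  Xp <- as.matrix(X %*% model$stem)
  up <- as.matrix(Xp %*% Matrix::t(model$stem)) * cfg$pool^2
  rc <- rowMeans((X - up)^2)
  eps <- matrix(rnorm(3 * 4), 3)
  bw <- deeprisk:::vae_backward(model, Xp, eps, recon_const = rc)
  ef <- deeprisk:::enc_forward(model, X)
  Z <- ef$mu + exp(ef$logvar / 2) * eps
  xh <- deeprisk:::dec_forward(model, Z)$Xhat
  full <- elbo_loss(X, xh, ef$mu, ef$logvar, cfg$beta)
  expect_equal(bw$loss$recon_loss, full$recon_loss, tolerance = 1e-12)
  expect_equal(bw$loss$total, full$total, tolerance = 1e-12)
})

test_that("training is deterministic and keeps the best-validation epoch", {
  beats <- make_small_beats(8)
  cfg <- vae_config("ecg", latent_dim = 4, hidden = 16, n_res = 1,
                    epochs = 15, batch_size = 4, beta = 0.2, seed = 6)
  m1 <- train_vae(beats, cfg)
  m2 <- train_vae(beats, cfg)
  expect_identical(m1$params, m2$params)
  expect_equal(nrow(m1$log), 15)
  expect_equal(min(m1$log$val_total), m1$log$val_total[m1$best_epoch])
  # the total column is recon + beta * kl by construction
  expect_equal(m1$log$total, m1$log$recon + 0.2 * m1$log$kl, tolerance = 1e-10)
})

test_that("training loss decreases substantially from start to finish", {
  beats <- make_small_beats(8)
  cfg <- vae_config("ecg", latent_dim = 6, hidden = 32, n_res = 1,
                    epochs = 40, batch_size = 4, beta = 0.05, seed = 6)
  m <- train_vae(beats, cfg)
  expect_lt(dplyr::last(m$log$recon), 0.6 * dplyr::first(m$log$recon))
})

test_that("encode/decode shapes honour the modality contract", {
  beats <- make_small_beats(6)
  cfg <- vae_config("ecg", latent_dim = 5, hidden = 16, n_res = 1,
                    epochs = 5, batch_size = 4, seed = 2)
  m <- train_vae(beats, cfg)
  code <- vae_encode(m, beats[[1]])
  expect_s3_class(code, "latent_code")
  expect_equal(dim(code$mu), c(1, 5))
  expect_equal(dim(code$logvar), c(1, 5))
  recon <- vae_decode(m, code$mu[1, ])
  expect_equal(dim(recon), c(12, 150))
  # sampling is reproducible through the seed
  a <- vae_encode(m, beats[[1]], sample = TRUE, seed = 3)
  b <- vae_encode(m, beats[[1]], sample = TRUE, seed = 3)
  expect_identical(a$z, b$z)
  expect_error(vae_decode(m, rnorm(7)), class = "deeprisk_shape_error")
})

test_that("cohort encoding returns one named latent column per dimension", {
  beats <- make_small_beats(6)
  cfg <- vae_config("ecg", latent_dim = 4, hidden = 8, n_res = 1,
                    epochs = 5, batch_size = 4, seed = 2)
  m <- train_vae(beats, cfg)
  Z <- encode_cohort(m, beats, prefix = "ecg")
  expect_s3_class(Z, "tbl_df")
  expect_equal(names(Z), sprintf("ecg_%03d", 0:3))
  expect_equal(nrow(Z), 6)
  # deterministic: posterior means, not samples
  expect_identical(Z, encode_cohort(m, beats, prefix = "ecg"))
})

test_that("reconstruction metrics satisfy the identity and sign cases", {
  set.seed(13)
  x <- matrix(rnorm(24), 12)
  x <- x - rowMeans(x)
  id <- reconstruction_metrics(x, x)
  expect_equal(id$pearson_r, 1)
  expect_equal(id$rmse, 0)
  neg <- reconstruction_metrics(x, -x)
  expect_equal(neg$pearson_r, -1)
  # formula oracle: per-lead covariance / sd product, then averaged
  y <- matrix(rnorm(24), 12)
  r_manual <- mean(vapply(1:12, function(i) {
    cov(x[i, ], y[i, ]) / (sd(x[i, ]) * sd(y[i, ]))
  }, numeric(1)))
  expect_equal(reconstruction_metrics(x, y)$pearson_r, r_manual,
               tolerance = 1e-12)
})

test_that("constant inputs flag the correlation as undefined", {
  x <- matrix(1, 12, 10)
  y <- matrix(rnorm(120), 12)
  expect_warning(out <- reconstruction_metrics(x, y), "constant")
  expect_true(is.na(out$pearson_r))
})

test_that("ssim is 1 for identical volumes and degrades with noise", {
  mi <- prep_mri(simulate_lge_volume(mri_sim_params(seed = 21)))
  same <- reconstruction_metrics(mi, mi)
  expect_equal(same$ssim, 1)
  noisy <- unclass(mi)
  set.seed(1)
  noisy[, , , 1] <- noisy[, , , 1] + rnorm(length(noisy[, , , 1]), sd = 0.2)
  worse <- reconstruction_metrics(mi, structure(noisy,
                                               channels = c("scan", "mask"),
                                               class = "model_input_volume"))
  expect_lt(worse$ssim, 0.9)
})

test_that("NaN-producing learning rates abort with a typed error", {
  beats <- make_small_beats(6)
  cfg <- vae_config("ecg", latent_dim = 4, hidden = 8, n_res = 1,
                    epochs = 10, batch_size = 4, seed = 2,
                    learning_rate = 1e100)
  expect_error(train_vae(beats, cfg), class = "deeprisk_training_error")
})
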