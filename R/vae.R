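# Residual beta-variational autoencoders for 1-D mean-beat ECGs and 3-D
# masked LGE volumes.
#
# The networks are implemented directly in R: a fixed average-pooling stem
# (for the volumetric modality) feeds dense layers with residual blocks;
# gradients are derived by hand and optimized with Adam.  The probabilistic
# contract is the usual one — the encoder outputs a diagonal-Gaussian
# posterior (mu, logvar), the decoder maps latent vectors back to the input
# domain, and training maximizes the beta-weighted evidence lower bound.

#' Configuration for a residual beta-VAE
#'
#' @param modality `"ecg"` (1-D mean beats, 12 x L) or `"mri"`
#'   (12 x 64 x 64 x 2 masked volumes).
#' @param input_shape Dimensions of one input; defaults to `c(12, 150)` for
#'   ECG and `c(12, 64, 64, 2)` for MRI.
#' @param latent_dim Latent dimensionality; defaults to 32 for ECG and 256
#'   for MRI.
#' @param hidden Width of the dense trunk (0 gives a purely linear
#'   encoder/decoder, useful for analytic checks).
#' @param n_res Residual blocks per trunk (default 2).
#' @param beta KL weight in the ELBO (default 1; 0 reduces training to a
#'   plain autoencoder loss).
#' @param pool In-plane average-pooling factor of the fixed stem (MRI only;
#'   default 4).
#' @param learning_rate Adam learning rate.
#' @param epochs Training epochs.
#' @param batch_size Minibatch size.
#' @param val_frac Fraction of samples held out for epoch selection.
#' @param activation `"lrelu"` (leaky ReLU, slope 0.1) or `"linear"`.
#' @param seed Integer seed controlling initialization, shuffling and the
#'   reparameterization draws.
#' @return An object of class `vae_config`.
#' @export
vae_config <- function(modality = c("ecg", "mri"), input_shape = NULL,
                       latent_dim = NULL, hidden = 64, n_res = 2, beta = 1,
                       pool = NULL, learning_rate = 1e-3, epochs = 50,
                       batch_size = 32, val_frac = 0.15,
                       activation = c("lrelu", "linear"), seed = 1L) {
  modality <- match.arg(modality)
  activation <- match.arg(activation)
  if (is.null(input_shape)) {
    input_shape <- if (modality == "ecg") c(12L, 150L) else c(12L, 64L, 64L, 2L)
  }
  if (is.null(latent_dim)) latent_dim <- if (modality == "ecg") 32L else 256L
  if (is.null(pool)) pool <- if (modality == "mri") 4L else 1L
  assert_that(latent_dim >= 1, "latent_dim must be >= 1")
  assert_that(beta >= 0, "beta must be non-negative")
  structure(list(modality = modality, input_shape = as.integer(input_shape),
                 input_dim = prod(input_shape),
                 latent_dim = as.integer(latent_dim), hidden = as.integer(hidden),
                 n_res = as.integer(n_res), beta = beta, pool = as.integer(pool),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), val_frac = val_frac,
                 activation = activation, seed = as.integer(seed)),
            class = "vae_config")
}

# Sparse average-pooling stem over the in-plane dimensions of the input
# shape.  Returns NULL when pooling is a no-op.
build_stem <- function(config) {
  p <- config$pool
  if (p <= 1) return(NULL)
  sh <- config$input_shape
  assert_that(length(sh) == 4, "pooling stem requires a 4-D input shape")
  assert_that(sh[2] %% p == 0 && sh[3] %% p == 0,
              "in-plane size must be divisible by the pool factor")
  idx <- arrayInd(seq_len(prod(sh)), .dim = sh)
  group <- (idx[, 1] - 1) +
    sh[1] * ((idx[, 2] - 1) %/% p) +
    sh[1] * (sh[2] %/% p) * ((idx[, 3] - 1) %/% p) +
    sh[1] * (sh[2] %/% p) * (sh[3] %/% p) * (idx[, 4] - 1) + 1
  Matrix::sparseMatrix(i = seq_len(prod(sh)), j = group, x = 1 / (p * p),
                       dims = c(prod(sh), max(group)))
}

act_fun <- function(x, kind) {
  if (kind == "linear") x else pmax(x, 0) + 0.1 * pmin(x, 0)
}
act_grad <- function(pre, kind) {
  if (kind == "linear") array(1, dim = dim(pre)) else
    ifelse(pre > 0, 1, 0.1)
}

init_mat <- function(nout, nin) {
  matrix(rnorm(nout * nin, sd = sqrt(2 / nin)), nrow = nout)
}

#' Initialize a residual beta-VAE
#'
#' @param config A [vae_config()].
#' @return An object of class `resvae` holding the configuration, the
#'   (seeded, random) parameters, and an empty training log.
#' @export
vae_init <- function(config) {
  stopifnot(inherits(config, "vae_config"))
  stem <- build_stem(config)
  Dp <- if (is.null(stem)) config$input_dim else ncol(stem)
  h <- config$hidden
  K <- config$latent_dim
  par <- with_seed(config$seed, {
    p <- list()
    if (h > 0) {
      p$enc.W_in <- init_mat(h, Dp); p$enc.b_in <- numeric(h)
      p$dec.V_in <- init_mat(h, K); p$dec.c_in <- numeric(h)
      for (i in seq_len(config$n_res)) {
        p[[paste0("enc.res", i, ".Wa")]] <- init_mat(h, h)
        p[[paste0("enc.res", i, ".ba")]] <- numeric(h)
        p[[paste0("enc.res", i, ".Wb")]] <- init_mat(h, h) * 0.1
        p[[paste0("enc.res", i, ".bb")]] <- numeric(h)
        p[[paste0("dec.res", i, ".Wa")]] <- init_mat(h, h)
        p[[paste0("dec.res", i, ".ba")]] <- numeric(h)
        p[[paste0("dec.res", i, ".Wb")]] <- init_mat(h, h) * 0.1
        p[[paste0("dec.res", i, ".bb")]] <- numeric(h)
      }
      p$enc.W_mu <- init_mat(K, h); p$enc.b_mu <- numeric(K)
      p$enc.W_lv <- init_mat(K, h) * 0.1; p$enc.b_lv <- numeric(K)
      p$dec.V_out <- init_mat(Dp, h); p$dec.c_out <- numeric(Dp)
    } else {
      p$enc.W_mu <- init_mat(K, Dp); p$enc.b_mu <- numeric(K)
      p$enc.W_lv <- init_mat(K, Dp) * 0.1; p$enc.b_lv <- numeric(K)
      p$dec.V_out <- init_mat(Dp, K); p$dec.c_out <- numeric(Dp)
    }
    p
  })
  structure(list(config = config, params = par, stem = stem,
                 log = tibble::tibble()),
            class = "resvae")
}

#' @export
print.resvae <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<resvae:%s> input %s -> latent %d (hidden %d, %d residual blocks, beta %g)\n",
              cfg$modality, paste(cfg$input_shape, collapse = "x"),
              cfg$latent_dim, cfg$hidden, cfg$n_res, cfg$beta))
  if (nrow(x$log) > 0) {
    cat(sprintf("  trained %d epochs; best val total %.5f\n",
                max(x$log$epoch), min(x$log$val_total)))
  }
  invisible(x)
}

# Coerce inputs to an n x D matrix in the model's flattening order.
as_vae_matrix <- function(x, config) {
  flatten_one <- function(v) {
    if (inherits(v, "mean_beat_set")) v <- v$beats
    if (inherits(v, "model_input_volume")) v <- unclass(v)
    as.numeric(v)
  }
  if (is.list(x) && !is.data.frame(x) &&
      !inherits(x, c("mean_beat_set", "model_input_volume"))) {
    X <- do.call(rbind, lapply(x, flatten_one))
  } else if (is.matrix(x) && ncol(x) == config$input_dim &&
             !identical(dim(x), as.integer(config$input_shape))) {
    X <- x
  } else {
    X <- matrix(flatten_one(x), nrow = 1)
  }
  if (ncol(X) != config$input_dim) {
    abort(sprintf("input has %d values per sample, expected %d",
                  ncol(X), config$input_dim),
          class = "deeprisk_shape_error")
  }
  X
}

add_bias <- function(A, b) sweep(A, 2, b, `+`)

# Encoder forward pass with activation caches.
enc_forward <- function(model, X) {
  Xp <- if (is.null(model$stem)) X else as.matrix(X %*% model$stem)
  enc_forward_pooled(model, Xp)
}

# Encoder forward on already-pooled input (training fast path: the fixed
# average-pool stem is applied once per dataset, not once per step).
enc_forward_pooled <- function(model, Xp) {
  p <- model$params; cfg <- model$config
  cache <- list(Xp = Xp)
  if (cfg$hidden > 0) {
    pre0 <- add_bias(Xp %*% t(p$enc.W_in), p$enc.b_in)
    H <- act_fun(pre0, cfg$activation)
    cache$pre0 <- pre0
    Hs <- list(H)
    for (i in seq_len(cfg$n_res)) {
      Wa <- p[[paste0("enc.res", i, ".Wa")]]; ba <- p[[paste0("enc.res", i, ".ba")]]
      Wb <- p[[paste0("enc.res", i, ".Wb")]]; bb <- p[[paste0("enc.res", i, ".bb")]]
      pre <- add_bias(H %*% t(Wa), ba)
      a <- act_fun(pre, cfg$activation)
      H <- H + add_bias(a %*% t(Wb), bb)
      cache[[paste0("pre", i)]] <- pre
      cache[[paste0("a", i)]] <- a
      Hs[[i + 1]] <- H
    }
    cache$Hs <- Hs
    top <- H
  } else {
    top <- Xp
  }
  cache$top <- top
  mu <- add_bias(top %*% t(p$enc.W_mu), p$enc.b_mu)
  lv <- add_bias(top %*% t(p$enc.W_lv), p$enc.b_lv)
  lv <- pmin(pmax(lv, -10), 10)  # numerical guard on the log-variance
  list(mu = mu, logvar = lv, cache = cache)
}

# Decoder forward pass with caches.  With unpool = FALSE the output stays
# in the pooled space (training fast path).
dec_forward <- function(model, Z, unpool = TRUE) {
  p <- model$params; cfg <- model$config
  cache <- list(Z = Z)
  if (cfg$hidden > 0) {
    pre0 <- add_bias(Z %*% t(p$dec.V_in), p$dec.c_in)
    G <- act_fun(pre0, cfg$activation)
    cache$pre0 <- pre0
    Gs <- list(G)
    for (i in seq_len(cfg$n_res)) {
      Wa <- p[[paste0("dec.res", i, ".Wa")]]; ba <- p[[paste0("dec.res", i, ".ba")]]
      Wb <- p[[paste0("dec.res", i, ".Wb")]]; bb <- p[[paste0("dec.res", i, ".bb")]]
      pre <- add_bias(G %*% t(Wa), ba)
      a <- act_fun(pre, cfg$activation)
      G <- G + add_bias(a %*% t(Wb), bb)
      cache[[paste0("pre", i)]] <- pre
      cache[[paste0("a", i)]] <- a
      Gs[[i + 1]] <- G
    }
    cache$Gs <- Gs
    top <- G
  } else {
    top <- Z
  }
  cache$top <- top
  Xp_hat <- add_bias(top %*% t(p$dec.V_out), p$dec.c_out)
  cache$Xp_hat <- Xp_hat
  Xhat <- if (is.null(model$stem) || !unpool) Xp_hat else
    as.matrix(Xp_hat %*% Matrix::t(model$stem)) * (model$config$pool^2)
  list(Xhat = Xhat, cache = cache)
}

#' Encode inputs to posterior latent codes
#'
#' Deterministically maps inputs to the diagonal-Gaussian posterior
#' parameters; a latent sample is drawn only on request, via the
#' reparameterization `z = mu + exp(logvar / 2) * eps`.
#'
#' @param model A `resvae`.
#' @param x A `mean_beat_set`, `model_input_volume`, n x D matrix, or list
#'   of such.
#' @param sample Draw a latent sample as well (default FALSE).
#' @param seed Seed for the sample draw.
#' @return A list of class `latent_code` with `mu`, `logvar` (n x K
#'   matrices) and optionally `z`.
#' @export
vae_encode <- function(model, x, sample = FALSE, seed = 1L) {
  stopifnot(inherits(model, "resvae"))
  X <- as_vae_matrix(x, model$config)
  fw <- enc_forward(model, X)
  out <- list(mu = fw$mu, logvar = fw$logvar)
  if (sample) {
    eps <- with_seed(seed, matrix(rnorm(length(fw$mu)), nrow = nrow(fw$mu)))
    out$z <- fw$mu + exp(fw$logvar / 2) * eps
  }
  structure(out, class = "latent_code")
}

#' Decode latent vectors back to the input domain
#'
#' @param model A `resvae`.
#' @param z Numeric vector of length `latent_dim` or an n x latent_dim
#'   matrix.
#' @return An n x D matrix of reconstructions (or a single input-shaped
#'   array when one vector is given).
#' @export
vae_decode <- function(model, z) {
  stopifnot(inherits(model, "resvae"))
  single <- is.null(dim(z))
  if (single) z <- matrix(z, nrow = 1)
  if (ncol(z) != model$config$latent_dim) {
    abort(sprintf("latent vector has length %d, expected %d",
                  ncol(z), model$config$latent_dim),
          class = "deeprisk_shape_error")
  }
  Xhat <- dec_forward(model, z)$Xhat
  if (single) array(Xhat[1, ], dim = model$config$input_shape) else Xhat
}

#' Evidence-lower-bound components
#'
#' `recon_loss` is the mean squared reconstruction error,
#' `kl` the closed-form KL divergence of the diagonal-Gaussian posterior
#' from the standard normal, `0.5 * sum(mu^2 + exp(logvar) - 1 - logvar)`
#' averaged over samples, and `total = recon_loss + beta * kl` exactly.
#'
#' @param x,xhat Matching input and reconstruction (matrices n x D).
#' @param mu,logvar Posterior parameters (n x K).
#' @param beta KL weight.
#' @return A list of class `elbo_report` with `recon_loss`, `kl`, `beta`,
#'   `total`.
#' @export
elbo_loss <- function(x, xhat, mu, logvar, beta = 1) {
  assert_that(all(dim(x) == dim(xhat)), "x and xhat shapes differ")
  recon <- mean((x - xhat)^2)
  kl <- mean(0.5 * rowSums(mu^2 + exp(logvar) - 1 - logvar))
  structure(list(recon_loss = recon, kl = kl, beta = beta,
                 total = recon + beta * kl),
            class = "elbo_report")
}

# One full forward/backward pass on a minibatch; returns loss components
# and the gradient list (same names as params).
#
# The pass runs in the pooled space: for the block-averaging stem the
# full-space MSE decomposes exactly as
#   mean_d (x - unpool(v))^2 = c + mean_g (pool(x) - v)^2,
# where c is the (parameter-free) within-block variance of x, so
# training on pooled inputs with the per-sample constants `recon_const`
# added back gives gradients and reported losses identical to the
# full-space pass, without any stem multiplication per step.
vae_backward <- function(model, Xp, eps, recon_const = 0) {
  p <- model$params; cfg <- model$config
  n <- nrow(Xp); G <- ncol(Xp)
  ef <- enc_forward_pooled(model, Xp)
  mu <- ef$mu; lv <- ef$logvar
  sig <- exp(lv / 2)
  Z <- mu + sig * eps
  df <- dec_forward(model, Z, unpool = FALSE)
  Xp_hat <- df$Xhat
  recon <- mean(recon_const) + mean((Xp - Xp_hat)^2)
  kl <- mean(0.5 * rowSums(mu^2 + exp(lv) - 1 - lv))
  loss <- structure(list(recon_loss = recon, kl = kl, beta = cfg$beta,
                         total = recon + cfg$beta * kl),
                    class = "elbo_report")

  g <- list()
  # ----- decoder backward -----
  dXp_hat <- 2 * (Xp_hat - Xp) / (n * G)
  top <- df$cache$top
  g$dec.V_out <- t(dXp_hat) %*% top
  g$dec.c_out <- colSums(dXp_hat)
  dTop <- dXp_hat %*% p$dec.V_out
  if (cfg$hidden > 0) {
    for (i in rev(seq_len(cfg$n_res))) {
      Wa <- p[[paste0("dec.res", i, ".Wa")]]; Wb <- p[[paste0("dec.res", i, ".Wb")]]
      a <- df$cache[[paste0("a", i)]]; pre <- df$cache[[paste0("pre", i)]]
      Hin <- df$cache$Gs[[i]]
      g[[paste0("dec.res", i, ".Wb")]] <- t(dTop) %*% a
      g[[paste0("dec.res", i, ".bb")]] <- colSums(dTop)
      dpre <- (dTop %*% Wb) * act_grad(pre, cfg$activation)
      g[[paste0("dec.res", i, ".Wa")]] <- t(dpre) %*% Hin
      g[[paste0("dec.res", i, ".ba")]] <- colSums(dpre)
      dTop <- dTop + dpre %*% Wa
    }
    dpre0 <- dTop * act_grad(df$cache$pre0, cfg$activation)
    g$dec.V_in <- t(dpre0) %*% Z
    g$dec.c_in <- colSums(dpre0)
    dZ <- dpre0 %*% p$dec.V_in
  } else {
    dZ <- dTop
  }
  # ----- latent and KL -----
  dmu <- dZ + cfg$beta * mu / n
  dlv <- dZ * eps * sig / 2 + cfg$beta * (exp(lv) - 1) / (2 * n)
  # ----- encoder backward -----
  top_e <- ef$cache$top
  g$enc.W_mu <- t(dmu) %*% top_e
  g$enc.b_mu <- colSums(dmu)
  g$enc.W_lv <- t(dlv) %*% top_e
  g$enc.b_lv <- colSums(dlv)
  dTop <- dmu %*% p$enc.W_mu + dlv %*% p$enc.W_lv
  if (cfg$hidden > 0) {
    for (i in rev(seq_len(cfg$n_res))) {
      Wa <- p[[paste0("enc.res", i, ".Wa")]]; Wb <- p[[paste0("enc.res", i, ".Wb")]]
      a <- ef$cache[[paste0("a", i)]]; pre <- ef$cache[[paste0("pre", i)]]
      Hin <- ef$cache$Hs[[i]]
      g[[paste0("enc.res", i, ".Wb")]] <- t(dTop) %*% a
      g[[paste0("enc.res", i, ".bb")]] <- colSums(dTop)
      dpre <- (dTop %*% Wb) * act_grad(pre, cfg$activation)
      g[[paste0("enc.res", i, ".Wa")]] <- t(dpre) %*% Hin
      g[[paste0("enc.res", i, ".ba")]] <- colSums(dpre)
      dTop <- dTop + dpre %*% Wa
    }
    dpre0 <- dTop * act_grad(ef$cache$pre0, cfg$activation)
    g$enc.W_in <- t(dpre0) %*% ef$cache$Xp
    g$enc.b_in <- colSums(dpre0)
  }
  list(loss = loss, grads = g)
}

#' Train a residual beta-VAE
#'
#' Seeded minibatch training with Adam; the per-epoch ELBO components on
#' the training and validation split are logged, and the returned model
#' carries the weights of the epoch with the lowest validation total loss.
#'
#' @param x Training inputs (list of `mean_beat_set` /
#'   `model_input_volume`, or an n x D matrix).
#' @param config A [vae_config()].
#' @param verbose Print per-epoch losses.
#' @return A trained `resvae` whose `log` is a tibble with columns
#'   `epoch`, `recon`, `kl`, `total`, `val_recon`, `val_kl`, `val_total`.
#' @export
train_vae <- function(x, config, verbose = FALSE) {
  model <- vae_init(config)
  X <- as_vae_matrix(x, config)
  n <- nrow(X)
  assert_that(n >= 1, "need at least one training sample")
  n_val <- max(1L, as.integer(round(n * config$val_frac)))
  perm <- with_seed(derive_seed(config$seed, "split"), sample.int(n))
  if (n >= 7) {
    val_idx <- perm[seq_len(n_val)]
    tr_idx <- perm[-seq_len(n_val)]
  } else {
    val_idx <- tr_idx <- seq_len(n)
  }
  # pool the whole dataset once; per-sample within-block variances are the
  # constant part of the full-space reconstruction loss (see vae_backward)
  if (is.null(model$stem)) {
    Xp_all <- X
    rconst <- rep(0, n)
  } else {
    Xp_all <- as.matrix(X %*% model$stem)
    rconst <- numeric(n)
    for (i0 in seq(1, n, by = 64)) {
      ii <- i0:min(n, i0 + 63)
      up <- as.matrix(Xp_all[ii, , drop = FALSE] %*% Matrix::t(model$stem)) *
        (config$pool^2)
      rconst[ii] <- rowMeans((X[ii, , drop = FALSE] - up)^2)
    }
  }
  Xtr <- Xp_all[tr_idx, , drop = FALSE]
  Xval <- Xp_all[val_idx, , drop = FALSE]
  rc_tr <- rconst[tr_idx]
  rc_val <- rconst[val_idx]

  adam_m <- lapply(model$params, function(w) w * 0)
  adam_v <- lapply(model$params, function(w) w * 0)
  b1 <- 0.9; b2 <- 0.999; epsn <- 1e-8; step <- 0
  best <- list(val = Inf, params = model$params, epoch = 0L)
  log <- vector("list", config$epochs)

  for (ep in seq_len(config$epochs)) {
    ord <- with_seed(derive_seed(config$seed, paste0("shuffle", ep)),
                     sample.int(nrow(Xtr)))
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    ep_loss <- c(recon = 0, kl = 0, total = 0)
    for (bi in seq_along(batches)) {
      Xb <- Xtr[batches[[bi]], , drop = FALSE]
      eps <- with_seed(derive_seed(config$seed, paste0("eps", ep, "_", bi)),
                       matrix(rnorm(nrow(Xb) * config$latent_dim),
                              nrow = nrow(Xb)))
      bw <- vae_backward(model, Xb, eps, recon_const = rc_tr[batches[[bi]]])
      if (!is.finite(bw$loss$total)) {
        abort(sprintf("NaN/Inf loss at epoch %d batch %d (recon %.4g, kl %.4g)",
                      ep, bi, bw$loss$recon_loss, bw$loss$kl),
              class = "deeprisk_training_error")
      }
      step <- step + 1
      for (nm in names(bw$grads)) {
        gval <- bw$grads[[nm]]
        adam_m[[nm]] <- b1 * adam_m[[nm]] + (1 - b1) * gval
        adam_v[[nm]] <- b2 * adam_v[[nm]] + (1 - b2) * gval^2
        mhat <- adam_m[[nm]] / (1 - b1^step)
        vhat <- adam_v[[nm]] / (1 - b2^step)
        model$params[[nm]] <- model$params[[nm]] -
          config$learning_rate * mhat / (sqrt(vhat) + epsn)
      }
      w <- nrow(Xb) / nrow(Xtr)
      ep_loss <- ep_loss + w * c(bw$loss$recon_loss, bw$loss$kl, bw$loss$total)
    }
    # deterministic validation pass (z = mu), in the pooled space
    efv <- enc_forward_pooled(model, Xval)
    xv <- dec_forward(model, efv$mu, unpool = FALSE)$Xhat
    lv <- elbo_loss(Xval, xv, efv$mu, efv$logvar, config$beta)
    lv$recon_loss <- lv$recon_loss + mean(rc_val)
    lv$total <- lv$recon_loss + config$beta * lv$kl
    log[[ep]] <- tibble::tibble(epoch = ep, recon = unname(ep_loss[1]),
                                kl = unname(ep_loss[2]),
                                total = unname(ep_loss[3]),
                                val_recon = lv$recon_loss,
                                val_kl = lv$kl, val_total = lv$total)
    if (verbose) {
      message(sprintf("epoch %3d  train %.5f  val %.5f", ep, ep_loss[3],
                      lv$total))
    }
    if (lv$total < best$val) {
      best <- list(val = lv$total, params = model$params, epoch = ep)
    }
  }
  model$params <- best$params
  model$best_epoch <- best$epoch
  model$log <- dplyr::bind_rows(log)
  model
}

#' Extract posterior-mean latent features for a cohort
#'
#' @param model A trained `resvae`.
#' @param x List of inputs (one per patient) or n x D matrix.
#' @param prefix Column-name prefix (e.g. `"mri"` gives `mri_000`, ...).
#' @param patient_id Optional id column.
#' @return A tibble: `patient_id` (if given) plus one column per latent
#'   dimension.
#' @export
encode_cohort <- function(model, x, prefix = model$config$modality,
                          patient_id = NULL) {
  lc <- vae_encode(model, x)
  mu <- lc$mu
  colnames(mu) <- sprintf("%s_%03d", prefix, seq_len(ncol(mu)) - 1)
  out <- tibble::as_tibble(mu)
  if (!is.null(patient_id)) out <- dplyr::bind_cols(
    tibble::tibble(patient_id = patient_id), out)
  out
}

# Rows of the Jacobian d mu_j / d x for the selected latent dimensions,
# evaluated at a single input.  Returns a length(indices) x D matrix.
vae_mu_jacobian_rows <- function(model, x, latent_indices) {
  cfg <- model$config
  X <- as_vae_matrix(x, cfg)
  assert_that(nrow(X) == 1, "jacobian rows are computed for a single input")
  ef <- enc_forward(model, X)
  p <- model$params
  k <- length(latent_indices)
  sel <- matrix(0, nrow = k, ncol = cfg$latent_dim)
  sel[cbind(seq_len(k), latent_indices)] <- 1
  dTop <- sel %*% p$enc.W_mu          # k x h (or k x D')
  if (cfg$hidden > 0) {
    for (i in rev(seq_len(cfg$n_res))) {
      Wa <- p[[paste0("enc.res", i, ".Wa")]]; Wb <- p[[paste0("enc.res", i, ".Wb")]]
      pre <- ef$cache[[paste0("pre", i)]]
      dpre <- (dTop %*% Wb) * matrix(act_grad(pre, cfg$activation),
                                     nrow = k, ncol = ncol(dTop), byrow = TRUE)
      dTop <- dTop + dpre %*% Wa
    }
    dpre0 <- dTop * matrix(act_grad(ef$cache$pre0, cfg$activation),
                           nrow = k, ncol = ncol(dTop), byrow = TRUE)
    dXp <- dpre0 %*% p$enc.W_in
  } else {
    dXp <- dTop
  }
  if (is.null(model$stem)) as.matrix(dXp) else
    as.matrix(dXp %*% Matrix::t(model$stem))
}

#' Reconstruction quality metrics
#'
#' Pearson correlation (per lead, then averaged, for 12 x L beat matrices;
#' overall for volumes), root mean squared error, and — for volumetric
#' inputs — the structural similarity index averaged over slices (computed
#' on the scan channel with an 8 x 8 sliding window).
#'
#' @param x,xhat Original and reconstruction: `mean_beat_set`,
#'   `model_input_volume`, matrix or array (shapes must match).
#' @return A tibble with columns `pearson_r`, `rmse` and (volumes only)
#'   `ssim`.  `pearson_r` is `NA` with a warning when an input is constant.
#' @export
reconstruction_metrics <- function(x, xhat) {
  get_raw <- function(v) {
    if (inherits(v, "mean_beat_set")) return(v$beats)
    if (inherits(v, "model_input_volume")) return(unclass(v))
    v
  }
  a <- get_raw(x); b <- get_raw(xhat)
  assert_that(all(dim(a) == dim(b)), "shapes of x and xhat differ")
  rmse <- sqrt(mean((a - b)^2))
  saw_constant <- FALSE
  safe_cor <- function(u, v) {
    if (sd(u) == 0 || sd(v) == 0) {
      saw_constant <<- TRUE
      return(NA_real_)
    }
    cor(u, v)
  }
  finish <- function(out) {
    if (saw_constant) warn("constant input: Pearson correlation undefined")
    out
  }
  if (is.matrix(a) && nrow(a) == 12) {
    r <- mean(vapply(1:12, function(i) safe_cor(a[i, ], b[i, ]), numeric(1)))
    return(finish(tibble::tibble(pearson_r = r, rmse = rmse)))
  }
  dims <- dim(a)
  sc_a <- if (length(dims) == 4) a[, , , 1] else a
  sc_b <- if (length(dims) == 4) b[, , , 1] else b
  r <- safe_cor(as.numeric(sc_a), as.numeric(sc_b))
  ss <- mean(vapply(seq_len(dim(sc_a)[1]), function(s)
    ssim_2d(sc_a[s, , ], sc_b[s, , ]), numeric(1)))
  finish(tibble::tibble(pearson_r = r, rmse = rmse, ssim = ss))
}

# Mean structural similarity of two 2-D images on data range [0, 1],
# 8 x 8 box window, standard constants C1 = 0.01^2, C2 = 0.03^2.
ssim_2d <- function(a, b, win = 8) {
  C1 <- 0.01^2; C2 <- 0.03^2
  mu_a <- box_blur(a, win - 1)  # odd window: 7
  mu_b <- box_blur(b, win - 1)
  va <- box_blur(a * a, win - 1) - mu_a^2
  vb <- box_blur(b * b, win - 1) - mu_b^2
  vab <- box_blur(a * b, win - 1) - mu_a * mu_b
  s <- ((2 * mu_a * mu_b + C1) * (2 * vab + C2)) /
    ((mu_a^2 + mu_b^2 + C1) * (va + vb + C2))
  mean(s)
}

#' @export
tidy.resvae <- function(x, ...) x$log

#' @export
glance.resvae <- function(x, ...) {
  cfg <- x$config
  tibble::tibble(modality = cfg$modality, latent_dim = cfg$latent_dim,
                 hidden = cfg$hidden, n_res = cfg$n_res, beta = cfg$beta,
                 epochs_trained = if (nrow(x$log)) max(x$log$epoch) else 0L,
                 best_val_total = if (nrow(x$log)) min(x$log$val_total) else NA_real_)
}

#' Plot the training curve of a residual beta-VAE
#'
#' @param object A trained `resvae`.
#' @param ... Unused.
#' @return A ggplot of training and validation total loss per epoch.
#' @export
autoplot.resvae <- function(object, ...) {
  df <- object$log |>
    dplyr::select("epoch", train = "total", validation = "val_total") |>
    tidyr::pivot_longer(-"epoch", names_to = "split", values_to = "loss")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                   colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::labs(y = "ELBO loss (recon + beta*KL)")
}
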