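# Explainability: Shapley feature attributions for the tree ensemble,
# latent-traversal reconstructions from the VAEs, and gradient-based
# attention maps computed directly from the learned latent space.

#' Shapley feature attributions for risk predictions
#'
#' Tree-path-dependent Shapley values for every explained row.  Values are
#' on the log-odds (margin) scale: `sum(phi) + base_value` equals the
#' model's margin output for the row, and a positive value indicates a
#' feature pushing the predicted probability up.
#'
#' @param model A [train_classifier()] fit.
#' @param X Numeric matrix of rows to explain (model feature columns).
#' @return An object of class `attribution_set`: list with `phi` (n x p
#'   matrix), `base_value` (expected margin), `margin` (per-row model
#'   output) and `feature_names`.
#' @export
shapley_attributions <- function(model, X) {
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
  contrib <- predict(model$booster, X, predcontrib = TRUE)
  p <- ncol(contrib) - 1L
  phi <- contrib[, seq_len(p), drop = FALSE]
  base <- unname(contrib[1, p + 1L])
  structure(list(phi = phi, base_value = base,
                 margin = rowSums(contrib),
                 feature_names = colnames(contrib)[seq_len(p)]),
            class = "attribution_set")
}

#' @export
print.attribution_set <- function(x, ...) {
  cat(sprintf("<attribution_set> %d rows x %d features (base %.4f)\n",
              nrow(x$phi), ncol(x$phi), x$base_value))
  invisible(x)
}

#' @export
tidy.attribution_set <- function(x, ...) {
  tibble::as_tibble(x$phi) |>
    dplyr::mutate(row = dplyr::row_number()) |>
    tidyr::pivot_longer(-"row", names_to = "feature", values_to = "phi")
}

#' Rank the most important latent features per patient
#'
#' Ranks latent features by absolute attribution per explained row,
#' restricted to columns matching `latent_pattern`; ties break
#' deterministically toward the lower feature index.
#'
#' @param attributions An [shapley_attributions()] result or a numeric
#'   attribution matrix with column names.
#' @param m Number of latents to keep (default 10).
#' @param latent_pattern Regular expression selecting latent columns
#'   (default matches the `mri_...`/`ecg_...` naming of [encode_cohort()]).
#' @return An n x m character matrix of feature names (one ranking per
#'   row), with attribute `indices` holding the column indices.
#' @export
top_latents <- function(attributions, m = 10,
                        latent_pattern = "^(mri|ecg)_[0-9]+$") {
  phi <- if (inherits(attributions, "attribution_set")) attributions$phi
         else attributions
  lat_cols <- grep(latent_pattern, colnames(phi))
  assert_that(length(lat_cols) > 0, "no latent feature columns found")
  m <- min(m, length(lat_cols))
  idx <- t(apply(abs(phi[, lat_cols, drop = FALSE]), 1, function(a) {
    lat_cols[order(-a, seq_along(a))[seq_len(m)]]
  }))
  out <- matrix(colnames(phi)[idx], nrow = nrow(phi))
  attr(out, "indices") <- idx
  out
}

#' Latent traversal reconstructions
#'
#' Holds every latent coordinate of a base vector fixed and sweeps one
#' dimension across `offsets` standard deviations (SD estimated from the
#' cohort's posterior means), decoding each altered vector.  The base
#' point is the cohort-mean latent by default, or one patient's latent.
#'
#' @param model A trained `resvae`.
#' @param latents Matrix or tibble of cohort posterior means (n x
#'   latent_dim; latent columns are detected by name when a tibble from
#'   [encode_cohort()] is given).
#' @param latent_index Dimension to traverse (1-based).
#' @param offsets Offsets in SD units (default `-3:3`, including 0).
#' @param base `"mean"` (default) or a patient row index.
#' @return A list of class `traversal_set` with `latent_index`, `offsets`,
#'   `sd`, `base_vector` and `reconstructions` (list of input-shaped
#'   arrays, in offset order).
#' @export
latent_traversal <- function(model, latents, latent_index, offsets = -3:3,
                             base = "mean") {
  stopifnot(inherits(model, "resvae"))
  Z <- as_latent_matrix(latents, model$config$latent_dim)
  K <- model$config$latent_dim
  if (latent_index < 1 || latent_index > K) {
    abort(sprintf("latent_index %d out of range 1..%d", latent_index, K),
          class = "deeprisk_parameter_error")
  }
  sds <- apply(Z, 2, stats::sd)
  base_vec <- if (identical(base, "mean")) colMeans(Z) else Z[base, ]
  recons <- lapply(offsets, function(o) {
    z <- base_vec
    z[latent_index] <- z[latent_index] + o * sds[latent_index]
    vae_decode(model, z)
  })
  structure(list(latent_index = latent_index, offsets = offsets,
                 sd = sds[latent_index], base_vector = base_vec,
                 reconstructions = recons),
            class = "traversal_set")
}

as_latent_matrix <- function(latents, K) {
  if (is.data.frame(latents)) {
    lat_cols <- grep("^(mri|ecg)_[0-9]+$", names(latents), value = TRUE)
    if (length(lat_cols) == 0) {
      lat_cols <- names(latents)[vapply(latents, is.numeric, logical(1))]
    }
    latents <- as.matrix(latents[lat_cols])
  }
  assert_that(ncol(latents) == K,
              "latent matrix width does not match the model's latent_dim")
  latents
}

#' Gradient-based attention map from the latent space
#'
#' For each selected latent dimension, the gradient of the posterior mean
#' with respect to the input is computed by backpropagation through the
#' encoder; the absolute gradients are averaged over the selected
#' dimensions (typically the ten latents with the highest Shapley
#' importances) and min-max normalized to `[0, 1]`.  For the volumetric
#' modality the map is restricted to the scan channel.
#'
#' @param model A trained `resvae`.
#' @param x One input (`mean_beat_set`, `model_input_volume`, or array).
#' @param latent_indices Integer vector of latent dimensions (1-based).
#' @return A list of class `attention_map` with `map` (the input's spatial
#'   shape: 12 x L for ECG, 12 x 64 x 64 for MRI), `latent_indices`, and
#'   `modality`.
#' @export
gradient_attention_map <- function(model, x, latent_indices) {
  stopifnot(inherits(model, "resvae"))
  assert_that(length(latent_indices) >= 1, "latent_indices must be non-empty")
  K <- model$config$latent_dim
  assert_that(all(latent_indices >= 1 & latent_indices <= K),
              "latent index out of range")
  J <- vae_mu_jacobian_rows(model, x, latent_indices)
  g <- colMeans(abs(J))
  arr <- array(g, dim = model$config$input_shape)
  if (length(model$config$input_shape) == 4) {
    arr <- arr[, , , 1]  # scan channel only
  }
  mx <- max(arr)
  if (mx > 0) arr <- arr / mx
  structure(list(map = arr, latent_indices = latent_indices,
                 modality = model$config$modality),
            class = "attention_map")
}

#' Overlay an attention map on the original input
#'
#' Alpha-blends the heatmap over the original signal panel (ECG: per-lead
#' traces coloured by local attention) or slice montage (MRI: raster
#' overlay), with a fixed colour scale.
#'
#' @param map An [gradient_attention_map()] result.
#' @param original The original input the map was computed on.
#' @param alpha Maximum overlay opacity (MRI; default 0.6).
#' @return A ggplot object.
#' @export
plot_attention_overlay <- function(map, original, alpha = 0.6) {
  stopifnot(inherits(map, "attention_map"))
  if (map$modality == "ecg") {
    beats <- if (inherits(original, "mean_beat_set")) original$beats
             else original
    L <- ncol(beats)
    df <- tibble::tibble(
      lead = factor(rep(lead_names_12(), times = L), levels = lead_names_12()),
      sample = rep(seq_len(L), each = 12),
      value = as.numeric(beats),
      attention = as.numeric(map$map))
    ggplot2::ggplot(df, ggplot2::aes(x = .data$sample, y = .data$value,
                                     colour = .data$attention)) +
      ggplot2::geom_line(ggplot2::aes(group = 1)) +
      ggplot2::facet_wrap(~lead, ncol = 4) +
      ggplot2::scale_colour_gradient(low = "grey30", high = "red",
                                     limits = c(0, 1)) +
      ggplot2::labs(x = "sample", y = "normalized amplitude",
                    colour = "attention")
  } else {
    vol <- if (inherits(original, "model_input_volume"))
      unclass(original)[, , , 1] else original
    S <- dim(vol)[1]
    long <- function(a, nm) {
      tibble::tibble(slice = rep(seq_len(S), times = prod(dim(a)[2:3])),
                     row = rep(rep(seq_len(dim(a)[2]), each = S),
                               times = dim(a)[3]),
                     col = rep(seq_len(dim(a)[3]), each = S * dim(a)[2]),
                     value = as.numeric(a), layer = nm)
    }
    df <- long(vol, "scan")
    df$attention <- as.numeric(map$map)
    ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
      ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
      ggplot2::scale_fill_gradient(low = "black", high = "white",
                                   limits = c(0, 1)) +
      ggplot2::geom_raster(ggplot2::aes(alpha = .data$attention),
                           fill = "red") +
      ggplot2::scale_alpha(range = c(0, alpha), limits = c(0, 1)) +
      ggplot2::facet_wrap(~slice, ncol = 4) +
      ggplot2::scale_y_reverse() +
      ggplot2::labs(alpha = "attention", fill = "intensity")
  }
}

#' Plot latent-traversal reconstructions
#'
#' @param object A `traversal_set`.
#' @param slice For volumetric reconstructions, the slice to display
#'   (default mid-stack).
#' @param ... Unused.
#' @return A ggplot faceted by offset.
#' @export
autoplot.traversal_set <- function(object, slice = NULL, ...) {
  r1 <- object$reconstructions[[1]]
  if (length(dim(r1)) == 2) {
    dfs <- purrr::imap_dfr(object$reconstructions, function(r, i) {
      tibble::tibble(offset = object$offsets[i],
                     lead = factor(rep(lead_names_12(), times = ncol(r)),
                                   levels = lead_names_12()),
                     sample = rep(seq_len(ncol(r)), each = 12),
                     value = as.numeric(r))
    })
    ggplot2::ggplot(dplyr::filter(dfs, .data$lead == "II"),
                    ggplot2::aes(x = .data$sample, y = .data$value)) +
      ggplot2::geom_line() +
      ggplot2::facet_wrap(~offset, nrow = 1) +
      ggplot2::labs(title = sprintf("latent %d traversal (lead II)",
                                    object$latent_index))
  } else {
    s <- slice %||% ceiling(dim(r1)[1] / 2)
    dfs <- purrr::imap_dfr(object$reconstructions, function(r, i) {
      sl <- r[s, , , 1]
      tibble::tibble(offset = object$offsets[i],
                     row = rep(seq_len(nrow(sl)), times = ncol(sl)),
                     col = rep(seq_len(ncol(sl)), each = nrow(sl)),
                     value = as.numeric(sl))
    })
    ggplot2::ggplot(dfs, ggplot2::aes(x = .data$col, y = .data$row,
                                      fill = .data$value)) +
      ggplot2::geom_raster() +
      ggplot2::scale_fill_gradient(low = "black", high = "white") +
      ggplot2::facet_wrap(~offset, nrow = 1) +
      ggplot2::scale_y_reverse() +
      ggplot2::labs(title = sprintf("latent %d traversal (slice %d)",
                                    object$latent_index, s))
  }
}
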