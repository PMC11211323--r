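# Short-axis LGE volume preprocessing: myocardium segmentation (pluggable
# backends), ROI cropping, standardization to 12 x 64 x 64 with per-volume
# histogram equalization, and assembly of the masked two-channel model
# input.

#' Construct an LGE volume object
#'
#' @param intensities S x H x W numeric array.
#' @param spacing_mm Voxel spacing (depth, row, col) in millimetres.
#' @return An object of class `lge_volume`.
#' @export
lge_volume <- function(intensities, spacing_mm = c(10, 1.8, 1.8)) {
  assert_that(is.array(intensities) && length(dim(intensities)) == 3,
              "intensities must be a 3-D array")
  assert_that(all(spacing_mm > 0), "spacing must be positive")
  structure(list(intensities = intensities, spacing_mm = spacing_mm),
            class = "lge_volume")
}

as_lge_volume <- function(x) {
  if (inherits(x, "lge_volume")) return(x)
  if (inherits(x, "lge_sim")) return(lge_volume(x$volume, x$spacing_mm))
  if (is.array(x) && length(dim(x)) == 3) return(lge_volume(x))
  abort("cannot interpret input as an LGE volume")
}

# Separable box blur of a matrix with an odd window k (edge-replicated).
box_blur <- function(m, k) {
  if (k <= 1) return(m)
  pad <- k %/% 2
  smooth1 <- function(v) {
    vv <- c(rep(v[1], pad), v, rep(v[length(v)], pad))
    as.numeric(stats::filter(vv, rep(1 / k, k), sides = 2))[(pad + 1):(pad + length(v))]
  }
  m2 <- apply(m, 2, smooth1)
  t(apply(m2, 1, smooth1))
}

# Per-pixel feature stack for the trainable segmenter: intensities averaged
# over a four-level pyramid of receptive fields plus local contrast and
# normalized radial coordinates.
segmenter_features <- function(vol) {
  S <- dim(vol)[1]; H <- dim(vol)[2]; W <- dim(vol)[3]
  r <- sqrt(slice_radius2(H, W)) / (min(H, W) / 2)
  # per-feature full arrays so that row i of the output corresponds to
  # as.numeric(vol)[i] (native column-major order of the S x H x W array)
  mk <- function() array(0, dim = c(S, H, W))
  a2 <- mk(); a4 <- mk(); a8 <- mk(); atex <- mk(); ar <- mk(); asl <- mk()
  for (s in seq_len(S)) {
    sl <- vol[s, , ]
    b4 <- box_blur(sl, 7)
    a2[s, , ] <- box_blur(sl, 3)
    a4[s, , ] <- b4
    a8[s, , ] <- box_blur(sl, 15)
    atex[s, , ] <- box_blur(abs(sl - b4), 7)
    ar[s, , ] <- r
    asl[s, , ] <- (s - 1) / max(1, S - 1)
  }
  cbind(x1 = as.numeric(vol), x2 = as.numeric(a2), x4 = as.numeric(a4),
        x8 = as.numeric(a8), tex = as.numeric(atex), r = as.numeric(ar),
        r2 = as.numeric(ar)^2, slice = as.numeric(asl))
}

#' Train the myocardium segmenter on synthetic pairs
#'
#' A four-level image-pyramid feature extractor (box-filtered intensities
#' at growing receptive fields, local contrast, normalized radial
#' coordinates) feeding a per-pixel random-forest classifier, which
#' captures the non-monotonic intensity and radius profile of the
#' myocardial annulus.  Trained only on synthetic volume/mask pairs.
#'
#' @param volumes List of S x H x W arrays (or `lge_sim` objects).
#' @param masks List of matching binary masks; taken from the `lge_sim`
#'   objects when omitted.
#' @param n_pixels Pixels subsampled per volume for the fit (default 3000).
#' @param seed Integer seed for the subsampling.
#' @return An object of class `myo_segmenter`.
#' @export
train_segmenter <- function(volumes, masks = NULL, n_pixels = 3000, seed = 1L) {
  if (is.null(masks) && all(vapply(volumes, inherits, logical(1), "lge_sim"))) {
    masks <- lapply(volumes, `[[`, "mask")
  }
  vols <- lapply(volumes, function(v) as_lge_volume(v)$intensities)
  assert_that(length(vols) == length(masks), "need one mask per volume")
  rows <- with_seed(seed, {
    lapply(seq_along(vols), function(i) {
      f <- segmenter_features(vols[[i]])
      y <- as.numeric(masks[[i]])
      idx <- sample.int(nrow(f), min(n_pixels, nrow(f)))
      cbind(f[idx, , drop = FALSE], y = y[idx])
    })
  })
  dat <- as.data.frame(do.call(rbind, rows))
  dat$y <- factor(dat$y, levels = c(0, 1))
  fit <- ranger::ranger(y ~ ., data = dat, probability = TRUE,
                        num.trees = 100, num.threads = 1,
                        seed = derive_seed(seed, "segmenter_forest"))
  structure(list(forest = fit), class = "myo_segmenter")
}

predict_segmenter <- function(model, vol) {
  f <- as.data.frame(segmenter_features(vol))
  pr <- predict(model$forest, data = f, num.threads = 1)$predictions[, "1"]
  array(pr, dim = dim(vol))
}

#' Segment the myocardium of an LGE volume
#'
#' Returns a pixel-wise myocardium probability map.  Backends:
#' `"analytic"` reads the generator's true annulus geometry (synthetic data
#' only; pass the `lge_sim` object or its mask as `truth`); `"model"`
#' applies a [train_segmenter()] fit; `"file"` loads an externally
#' produced map from a NIfTI file.
#'
#' @param vol An `lge_volume`, `lge_sim` or 3-D array.
#' @param backend One of `"analytic"`, `"model"`, `"file"`.
#' @param truth For `"analytic"`: the `lge_sim` object or its binary mask.
#' @param model For `"model"`: a `myo_segmenter`.
#' @param file For `"file"`: path to a NIfTI probability map.
#' @return S x H x W array of probabilities in `[0, 1]`.
#' @export
segment_myocardium <- function(vol, backend = c("analytic", "model", "file"),
                               truth = NULL, model = NULL, file = NULL) {
  backend <- match.arg(backend)
  v <- as_lge_volume(vol)$intensities
  map <- switch(backend,
    analytic = {
      m <- if (inherits(vol, "lge_sim")) vol$mask else truth
      if (inherits(m, "lge_sim")) m <- m$mask
      assert_that(!is.null(m), "analytic backend needs generator truth")
      if (!all(dim(m) == dim(v))) {
        abort("truth mask shape does not match the volume",
              class = "deeprisk_shape_error")
      }
      array(as.numeric(m), dim = dim(v))
    },
    model = {
      assert_that(inherits(model, "myo_segmenter"),
                  "model backend needs a myo_segmenter")
      predict_segmenter(model, v)
    },
    file = {
      read_volume_nifti(file)$intensities
    })
  if (!all(dim(map) == dim(v))) {
    abort("probability map shape does not match the volume",
          class = "deeprisk_shape_error")
  }
  map
}

#' Crop a volume to the myocardium region of interest
#'
#' Computes the tight in-plane bounding box of all voxels with probability
#' at or above `threshold` across all slices, expands it by `margin`
#' pixels on each side (clipped to the frame), and applies the same crop to
#' every slice of the volume and the map.
#'
#' @param vol An `lge_volume` or 3-D array.
#' @param map Matching probability map.
#' @param threshold Probability threshold (default 0.5).
#' @param margin Margin in pixels added on each side before clipping
#'   (default 8).
#' @return List with cropped `volume`, `map`, and the `box` used
#'   (row_min, row_max, col_min, col_max).
#' @export
crop_roi <- function(vol, map, threshold = 0.5, margin = 8) {
  v <- as_lge_volume(vol)$intensities
  hit <- which(map >= threshold, arr.ind = TRUE)
  if (nrow(hit) == 0) {
    abort("no voxel reaches the probability threshold: no myocardium found",
          class = "deeprisk_no_myocardium")
  }
  H <- dim(v)[2]; W <- dim(v)[3]
  box <- c(row_min = max(1L, min(hit[, 2]) - margin),
           row_max = min(H, max(hit[, 2]) + margin),
           col_min = max(1L, min(hit[, 3]) - margin),
           col_max = min(W, max(hit[, 3]) + margin))
  list(volume = v[, box["row_min"]:box["row_max"],
                  box["col_min"]:box["col_max"], drop = FALSE],
       map = map[, box["row_min"]:box["row_max"],
                 box["col_min"]:box["col_max"], drop = FALSE],
       box = box)
}

# Rank-based per-volume histogram equalization: maps intensities to an
# approximately uniform distribution on [0, 1] while preserving the voxel
# rank order.  A constant volume maps to a constant.
equalize_volume <- function(v) {
  n <- length(v)
  if (diff(range(v)) == 0) return(array(0.5, dim = dim(v)))
  array((rank(v, ties.method = "average") - 0.5) / n, dim = dim(v))
}

#' Standardize a cropped volume to 12 x 64 x 64
#'
#' Slice count is harmonized to 12 (centre-crop when more, symmetric
#' zero-pad — with zero mask — when fewer), slices are bilinearly resized
#' in-plane to 64 x 64 (nearest-neighbour for the mask, then
#' re-binarized at 0.5), and per-volume histogram equalization maps
#' intensities to `[0, 1]`.
#'
#' @param vol Cropped S x H x W array.
#' @param map Cropped probability map.
#' @param n_slices Target slice count (default 12).
#' @param size Target in-plane size (default 64).
#' @param threshold Binarization threshold for the mask (default 0.5).
#' @param equalize Apply histogram equalization (default TRUE).
#' @return List with `volume` (12 x 64 x 64, in `[0, 1]`) and `mask`
#'   (binary 12 x 64 x 64).
#' @export
standardize_volume <- function(vol, map, n_slices = 12, size = 64,
                               threshold = 0.5, equalize = TRUE) {
  v <- as_lge_volume(vol)$intensities
  S <- dim(v)[1]
  # slice harmonization
  if (S > n_slices) {
    keep <- seq_len(n_slices) + (S - n_slices) %/% 2
    v <- v[keep, , , drop = FALSE]
    map <- map[keep, , , drop = FALSE]
  } else if (S < n_slices) {
    pad_lo <- (n_slices - S) %/% 2
    newv <- array(0, dim = c(n_slices, dim(v)[2], dim(v)[3]))
    newm <- array(0, dim = c(n_slices, dim(v)[2], dim(v)[3]))
    newv[pad_lo + seq_len(S), , ] <- v
    newm[pad_lo + seq_len(S), , ] <- map
    v <- newv; map <- newm
  }
  out_v <- array(0, dim = c(n_slices, size, size))
  out_m <- array(0, dim = c(n_slices, size, size))
  for (s in seq_len(n_slices)) {
    out_v[s, , ] <- EBImage::resize(v[s, , ], w = size, h = size,
                                    filter = "bilinear")
    out_m[s, , ] <- EBImage::resize(map[s, , ], w = size, h = size,
                                    filter = "none")
  }
  out_m <- (out_m >= threshold) * 1
  if (equalize) {
    out_v <- equalize_volume(out_v)
  } else {
    rng <- range(out_v)
    if (diff(rng) > 0) out_v <- (out_v - rng[1]) / diff(rng)
  }
  list(volume = out_v, mask = out_m)
}

#' Assemble the two-channel model input
#'
#' Channel 1 is the preprocessed scan zeroed outside the myocardium wall;
#' channel 2 is the binary myocardium mask.
#'
#' @param vol64 12 x 64 x 64 standardized scan.
#' @param mask64 12 x 64 x 64 binary mask.
#' @return An object of class `model_input_volume`: a 12 x 64 x 64 x 2
#'   array with attribute `channels = c("scan", "mask")`.
#' @export
assemble_model_input <- function(vol64, mask64) {
  if (!all(dim(vol64) == dim(mask64))) {
    abort("scan and mask shapes differ", class = "deeprisk_shape_error")
  }
  out <- array(0, dim = c(dim(vol64), 2))
  out[, , , 1] <- vol64 * mask64
  out[, , , 2] <- mask64
  structure(out, channels = c("scan", "mask"), class = "model_input_volume")
}

#' Full MRI preprocessing chain
#'
#' Segmentation (chosen backend) -> ROI crop -> standardization to
#' 12 x 64 x 64 -> masked two-channel assembly.
#'
#' @inheritParams segment_myocardium
#' @inheritParams crop_roi
#' @param ... Passed to [standardize_volume()].
#' @return A `model_input_volume` (12 x 64 x 64 x 2).
#' @export
prep_mri <- function(vol, backend = "analytic", truth = NULL, model = NULL,
                     file = NULL, threshold = 0.5, margin = 8, ...) {
  map <- segment_myocardium(vol, backend = backend, truth = truth,
                            model = model, file = file)
  cr <- crop_roi(vol, map, threshold = threshold, margin = margin)
  st <- standardize_volume(cr$volume, cr$map, threshold = threshold, ...)
  assemble_model_input(st$volume, st$mask)
}

#' Dice overlap between two binary masks
#'
#' @param a,b Binary arrays of identical shape.
#' @return Dice coefficient in `[0, 1]` (1 when both masks are empty).
#' @export
dice_coefficient <- function(a, b) {
  a <- a > 0.5; b <- b > 0.5
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}
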