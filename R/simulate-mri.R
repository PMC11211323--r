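# Synthetic short-axis LGE-like volume generator.
#
# Each slice holds an annular "myocardium" (dark on LGE), a bright blood
# pool inside it, and optional hyper-enhanced lesion blobs drawn strictly
# inside the annulus until a target enhanced fraction is reached.  The true
# annulus mask and realized lesion fraction are returned so downstream
# stages can be checked against exact geometry.

#' Parameters for the synthetic LGE volume generator
#'
#' @param n_slices Number of short-axis slices (default 12).
#' @param height,width In-plane dimensions in pixels.
#' @param spacing_mm Voxel spacing as (depth, row, col) in millimetres;
#'   in-plane spacing for clinical short-axis LGE is typically 1.5-2.4 mm
#'   with 10 mm slice depth.
#' @param ring_radii Optional `n_slices x 2` matrix of (inner, outer) radii
#'   in pixels; defaults to a mild apex-to-base taper.
#' @param ring_scale Scalar multiplier applied to the default radii
#'   (patient-level heart-size variation); ignored when `ring_radii` is
#'   given.
#' @param lesion_count Number of distinct lesion foci grown to reach
#'   `lesion_fraction` (default 4; ignored when `lesion_fraction = 0`).
#' @param lesion_fraction Target fraction of myocardium voxels that are
#'   hyper-enhanced, in `[0, 1]`.
#' @param intensity_levels Named list with `background`, `blood`,
#'   `myocardium`, `lesion` mean intensities and `noise_sd`.
#' @param seed Integer seed.
#'
#' @return An object of class `mri_sim_params`.
#' @export
mri_sim_params <- function(n_slices = 12, height = 80, width = 80,
                           spacing_mm = c(10, 1.8, 1.8), ring_radii = NULL,
                           ring_scale = 1, lesion_count = 4, lesion_fraction = 0,
                           intensity_levels = list(background = 0.05,
                                                   blood = 0.7,
                                                   myocardium = 0.2,
                                                   lesion = 0.8,
                                                   noise_sd = 0.03),
                           seed = 1L) {
  assert_that(is_scalar_num(n_slices) && n_slices >= 1, "n_slices must be >= 1")
  assert_that(is_scalar_num(height) && height >= 16 && is_scalar_num(width) &&
                width >= 16, "height/width must be >= 16")
  assert_that(length(spacing_mm) == 3 && all(spacing_mm > 0),
              "spacing_mm must be three positive numbers")
  assert_that(is_scalar_num(lesion_fraction) && lesion_fraction >= 0 &&
                lesion_fraction <= 1,
              "lesion_fraction must lie in [0, 1]")
  assert_that(is_scalar_num(lesion_count) && lesion_count >= 0,
              "lesion_count must be non-negative")
  if (is.null(ring_radii)) {
    r_out <- seq(0.18, 0.28, length.out = n_slices) * min(height, width)
    r_in <- r_out - seq(0.07, 0.10, length.out = n_slices) * min(height, width)
    ring_radii <- cbind(inner = r_in, outer = r_out) * ring_scale
  }
  assert_that(is.matrix(ring_radii) && nrow(ring_radii) == n_slices &&
                ncol(ring_radii) == 2,
              "ring_radii must be an n_slices x 2 matrix")
  assert_that(all(ring_radii[, 1] < ring_radii[, 2]),
              "inner radius must be smaller than outer radius on every slice")
  structure(list(n_slices = as.integer(n_slices), height = as.integer(height),
                 width = as.integer(width), spacing_mm = spacing_mm,
                 ring_radii = ring_radii, lesion_count = as.integer(lesion_count),
                 lesion_fraction = lesion_fraction,
                 intensity_levels = intensity_levels, seed = as.integer(seed)),
            class = "mri_sim_params")
}

# Squared in-plane distance from the slice centre, as an H x W matrix.
slice_radius2 <- function(height, width) {
  cy <- (height + 1) / 2
  cx <- (width + 1) / 2
  outer((seq_len(height) - cy)^2, (seq_len(width) - cx)^2, `+`)
}

#' Simulate a short-axis LGE-like volume
#'
#' @param params An [mri_sim_params()] object.
#' @return A list of class `lge_sim` with elements `volume`
#'   (S x H x W array), `mask` (binary annulus, 1 = myocardium),
#'   `lesion_mask` (binary, subset of `mask`), `lesion_fraction`
#'   (realized enhanced fraction) and `spacing_mm`.
#' @export
simulate_lge_volume <- function(params) {
  stopifnot(inherits(params, "mri_sim_params"))
  S <- params$n_slices; H <- params$height; W <- params$width
  lv <- params$intensity_levels
  r2 <- slice_radius2(H, W)
  vol <- array(lv$background, dim = c(S, H, W))
  mask <- array(0L, dim = c(S, H, W))
  lesion <- array(0L, dim = c(S, H, W))
  for (s in seq_len(S)) {
    rin <- params$ring_radii[s, 1]; rout <- params$ring_radii[s, 2]
    ring <- r2 >= rin^2 & r2 <= rout^2
    blood <- r2 < rin^2
    sl <- matrix(lv$background, H, W)
    sl[blood] <- lv$blood
    sl[ring] <- lv$myocardium
    vol[s, , ] <- sl
    mask[s, , ][ring] <- 1L
  }
  n_myo <- sum(mask)
  frac <- 0
  with_seed(params$seed, {
    if (params$lesion_fraction > 0 && params$lesion_count > 0) {
      # place foci at random ring voxels, then grow all radii together
      # until the enhanced fraction reaches the target
      foci <- lapply(seq_len(params$lesion_count), function(i) {
        s <- sample.int(S, 1)
        idx <- which(mask[s, , ] == 1L)
        p <- idx[sample.int(length(idx), 1)]
        c(s = s, row = (p - 1) %% H + 1, col = (p - 1) %/% H + 1)
      })
      radius <- 1
      slice_step <- 4  # growing foci reach a neighbouring slice every 4 px
      repeat {
        cand <- array(0L, dim = c(S, H, W))
        for (f in foci) {
          ds_max <- floor(radius / slice_step)
          for (s2 in max(1, f["s"] - ds_max):min(S, f["s"] + ds_max)) {
            r_s2 <- radius^2 - ((s2 - f["s"]) * slice_step)^2
            if (r_s2 <= 0) next
            r_s <- sqrt(r_s2)
            rows <- max(1, f["row"] - ceiling(r_s)):min(H, f["row"] + ceiling(r_s))
            cols <- max(1, f["col"] - ceiling(r_s)):min(W, f["col"] + ceiling(r_s))
            d2 <- outer((rows - f["row"])^2, (cols - f["col"])^2, `+`)
            hit <- d2 <= r_s2
            sub <- cand[s2, rows, cols]
            sub[hit] <- 1L
            cand[s2, rows, cols] <- sub
          }
        }
        cand <- cand * mask  # lesions never leave the myocardium
        frac_cand <- sum(cand) / n_myo
        if (frac_cand >= params$lesion_fraction || radius > max(H, W)) {
          lesion <- cand
          frac <- frac_cand
          break
        }
        radius <- radius + 0.25
      }
      vol[lesion == 1L] <- lv$lesion
    }
    if (lv$noise_sd > 0) {
      vol <- vol + array(rnorm(length(vol), sd = lv$noise_sd), dim = dim(vol))
    }
  })
  structure(list(volume = vol, mask = mask, lesion_mask = lesion,
                 lesion_fraction = frac, spacing_mm = params$spacing_mm,
                 ring_radii = params$ring_radii),
            class = "lge_sim")
}
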