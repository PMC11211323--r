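# File interchange: per-lead CSV ECGs, NIfTI volumes and model inputs
# with JSON sidecars, latent/clinical CSV tables and cohort manifests.

#' Write an ECG record as per-lead CSV
#'
#' One column per lead plus a `sample` column; the sampling rate is stored
#' in a JSON sidecar next to the CSV.
#'
#' @param rec An [ecg_record()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ecg_csv <- function(rec, path) {
  stopifnot(inherits(rec, "ecg_record"))
  df <- data.frame(sample = seq_len(ncol(rec$signals)), t(rec$signals),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(fs_hz = rec$fs_hz, lead_names = rec$lead_names,
                            unit = "mV"),
                       sidecar_path(path), auto_unbox = TRUE)
  invisible(path)
}

#' Read a per-lead CSV ECG
#'
#' @param path CSV path written by [write_ecg_csv()] (or any table with a
#'   `sample` column and one column per lead).
#' @param fs_hz Sampling rate; taken from the JSON sidecar when present.
#' @return An [ecg_record()].
#' @export
read_ecg_csv <- function(path, fs_hz = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  sc <- sidecar_path(path)
  if (is.null(fs_hz) && file.exists(sc)) {
    fs_hz <- jsonlite::read_json(sc)$fs_hz
  }
  assert_that(!is.null(fs_hz), "fs_hz not given and no sidecar found")
  leads <- setdiff(names(df), "sample")
  ecg_record(t(as.matrix(df[leads])), fs_hz = fs_hz, lead_names = leads)
}

sidecar_path <- function(path) sub("\\.[^.]+$", ".json", path)

#' Write a mean-beat set as CSV plus JSON sidecar
#'
#' @param mbs A `mean_beat_set`.
#' @param path Output CSV path (12 rows x L columns).
#' @return `path`, invisibly.
#' @export
write_mean_beats <- function(mbs, path) {
  stopifnot(inherits(mbs, "mean_beat_set"))
  utils::write.csv(data.frame(lead = rownames(mbs$beats), mbs$beats,
                              check.names = FALSE),
                   path, row.names = FALSE)
  jsonlite::write_json(list(fs_hz = mbs$fs_hz,
                            alignment_index = mbs$alignment_index,
                            n_beats = mbs$n_beats),
                       sidecar_path(path), auto_unbox = TRUE)
  invisible(path)
}

#' Read a mean-beat set from CSV
#'
#' @param path CSV written by [write_mean_beats()].
#' @return A `mean_beat_set`.
#' @export
read_mean_beats <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  meta <- jsonlite::read_json(sidecar_path(path))
  b <- as.matrix(df[setdiff(names(df), "lead")])
  rownames(b) <- df$lead
  colnames(b) <- NULL
  structure(list(beats = b, fs_hz = meta$fs_hz,
                 alignment_index = meta$alignment_index,
                 n_beats = meta$n_beats),
            class = "mean_beat_set")
}

#' Write a volume (or mask) as NIfTI
#'
#' @param vol An `lge_volume`, `lge_sim` or 3-D array; spacing is stored
#'   in the header (slice depth maps to the third pixdim).
#' @param path Output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume_nifti <- function(vol, path) {
  v <- as_lge_volume(vol)
  # store as (row, col, slice) so in-plane spacing occupies pixdim 1-2
  arr <- aperm(v$intensities, c(2, 3, 1))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(v$spacing_mm[2], v$spacing_mm[3], v$spacing_mm[1])
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume
#'
#' @param path NIfTI path (written by [write_volume_nifti()] or external).
#' @return An `lge_volume` with spacing from the header.
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  arr <- aperm(array(as.numeric(img), dim = dim(img)), c(3, 1, 2))
  lge_volume(arr, spacing_mm = c(pd[3], pd[1], pd[2]))
}

#' Write a model input volume as NIfTI plus sidecar
#'
#' The two channels occupy the 4th dimension; the sidecar records the
#' channel order (`scan`, `mask`).
#'
#' @param miv A `model_input_volume`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_input <- function(miv, path) {
  stopifnot(inherits(miv, "model_input_volume"))
  arr <- aperm(unclass(miv), c(2, 3, 1, 4))
  RNifti::writeNifti(RNifti::asNifti(arr), path)
  jsonlite::write_json(list(channels = attr(miv, "channels"),
                            dim_order = c("row", "col", "slice", "channel")),
                       sidecar_path(path), auto_unbox = TRUE)
  invisible(path)
}

#' Read a model input volume
#'
#' @param path NIfTI written by [write_model_input()].
#' @return A `model_input_volume`.
#' @export
read_model_input <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- aperm(array(as.numeric(img), dim = dim(img)), c(3, 1, 2, 4))
  structure(arr, channels = c("scan", "mask"), class = "model_input_volume")
}

#' Write a synthetic cohort to disk
#'
#' ECGs as per-lead CSV, volumes and masks as NIfTI, the clinical table
#' and outcomes as CSV, plus a manifest CSV linking patient id to paths.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return The manifest tibble, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "deeprisk_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- cohort$patients$patient_id
  man <- tibble::tibble(
    patient_id = ids,
    ecg_path = file.path(dir, paste0(ids, "_ecg.csv")),
    volume_path = file.path(dir, paste0(ids, "_lge.nii.gz")),
    mask_path = file.path(dir, paste0(ids, "_mask.nii.gz"))
  )
  for (i in seq_along(ids)) {
    write_ecg_csv(cohort$ecg[[i]], man$ecg_path[i])
    write_volume_nifti(cohort$mri[[i]], man$volume_path[i])
    write_volume_nifti(lge_volume(cohort$mri[[i]]$mask,
                                  cohort$mri[[i]]$spacing_mm),
                       man$mask_path[i])
  }
  utils::write.csv(cohort$clinical, file.path(dir, "clinical.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$patients[c("patient_id", "outcome")],
                   file.path(dir, "outcomes.csv"), row.names = FALSE)
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(man)
}
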