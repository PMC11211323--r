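# Workbench: configuration schema, seed derivation, stage caching and the
# end-to-end reproducible run (simulate -> preprocess -> VAEs -> encode ->
# risk branches -> predict -> evaluate -> explain).

pipeline_schema <- function() {
  list(
    seed = NULL,
    cohort = list(n_patients = NULL, intercept = NULL, b_lesion = NULL,
                  b_qrs = NULL, b_clinical = NULL, missing_rate = NULL,
                  mri_size = NULL, fs_hz = NULL),
    split = list(dev_frac = NULL),
    vae_ecg = list(latent_dim = NULL, hidden = NULL, n_res = NULL,
                   beta = NULL, epochs = NULL, batch_size = NULL,
                   learning_rate = NULL),
    vae_mri = list(latent_dim = NULL, hidden = NULL, n_res = NULL,
                   beta = NULL, epochs = NULL, batch_size = NULL,
                   learning_rate = NULL, pool = NULL),
    tune = list(enabled = NULL, n_trials = NULL, k_folds = NULL),
    model = list(max_depth = NULL, eta = NULL, nrounds = NULL,
                 subsample = NULL, min_child_weight = NULL, alpha = NULL,
                 lambda = NULL),
    evaluate = list(n_boot = NULL),
    explain = list(enabled = NULL, m_top = NULL)
  )
}

check_config_keys <- function(config, schema, path = "") {
  for (nm in names(config)) {
    here <- if (nzchar(path)) paste0(path, ".", nm) else nm
    if (!nm %in% names(schema)) {
      abort(sprintf("unknown configuration key: %s", here),
            class = "deeprisk_config_error")
    }
    if (is.list(schema[[nm]]) && !is.null(config[[nm]])) {
      if (!is.list(config[[nm]])) {
        abort(sprintf("configuration key %s must be a section", here),
              class = "deeprisk_config_error")
      }
      check_config_keys(config[[nm]], schema[[nm]], here)
    }
  }
}

#' Build a validated pipeline configuration
#'
#' Single hierarchical configuration for [run_deeprisk_pipeline()]; any
#' key outside the documented schema is rejected before any computation.
#' All per-stage seeds derive from the one master `seed`.
#'
#' @param ... Named sections / values overriding the defaults (see
#'   Details).  Sections: `cohort` (simulation), `split` (`dev_frac`),
#'   `vae_ecg` / `vae_mri`, `tune`, `model`, `evaluate`, `explain`.
#' @param seed Master seed.
#' @return A list of class `deeprisk_config`.
#' @export
pipeline_config <- function(..., seed = 1L) {
  user <- list(...)
  if (length(user) == 1 && is.null(names(user)) && is.list(user[[1]])) {
    user <- user[[1]]
  }
  defaults <- list(
    seed = as.integer(seed),
    cohort = list(n_patients = 120, intercept = qlogis(0.2), b_lesion = 2,
                  b_qrs = 0.5, b_clinical = 0.5, missing_rate = 0.1,
                  mri_size = 80, fs_hz = 500),
    split = list(dev_frac = 2 / 3),
    vae_ecg = list(latent_dim = 16, hidden = 64, n_res = 1, beta = 0.05,
                   epochs = 40, batch_size = 32, learning_rate = 1e-3),
    vae_mri = list(latent_dim = 32, hidden = 128, n_res = 1, beta = 0.005,
                   epochs = 60, batch_size = 32, learning_rate = 3e-3,
                   pool = 4),
    tune = list(enabled = FALSE, n_trials = 15, k_folds = 5),
    model = list(max_depth = 3, eta = 0.1, nrounds = 150, subsample = 0.9,
                 min_child_weight = 1, alpha = 0, lambda = 1),
    evaluate = list(n_boot = 500),
    explain = list(enabled = TRUE, m_top = 10)
  )
  check_config_keys(user, pipeline_schema())
  cfg <- utils::modifyList(defaults, user)
  structure(cfg, class = "deeprisk_config")
}

cache_stage <- function(dir, name, expr, resume = TRUE) {
  if (is.null(dir)) return(force(expr))
  path <- file.path(dir, "cache", paste0(name, ".rds"))
  if (resume && file.exists(path)) return(readRDS(path))
  val <- force(expr)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  saveRDS(val, path)
  val
}

#' Run the full multimodal risk pipeline
#'
#' Simulates a cohort, preprocesses every ECG and volume, trains the two
#' beta-VAEs on the development split, extracts latents, trains the four
#' risk branches (multimodal, MRI, ECG, clinical), predicts the external
#' split, evaluates with bootstrap CIs and DeLong comparisons, and runs
#' the explainability stage.  Every stage is seeded from the master seed
#' and (when `out_dir` is given) cached, so re-running reproduces the
#' results exactly.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional run directory for caches, CSV outputs and the
#'   run manifest.
#' @param resume Reuse cached stage outputs when present (default TRUE).
#' @param verbose Print stage progress.
#' @return A list of class `deeprisk_run`: `config`, `cohort` truth table,
#'   `dev_ids`/`ext_ids`, `vae_ecg`, `vae_mri`, `models` (per branch),
#'   `predictions` (external cohort), `metrics`, `delong` and `explain`.
#' @export
run_deeprisk_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                                  resume = TRUE, verbose = FALSE) {
  stopifnot(inherits(config, "deeprisk_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  seed <- config$seed
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)

  say("stage 1/8: simulate cohort")
  cohort <- cache_stage(out_dir, "cohort", resume = resume, expr = {
    cp <- cohort_sim_params(
      n_patients = config$cohort$n_patients,
      intercept = config$cohort$intercept,
      b_lesion = config$cohort$b_lesion, b_qrs = config$cohort$b_qrs,
      b_clinical = config$cohort$b_clinical,
      missing_rate = config$cohort$missing_rate,
      fs_hz = config$cohort$fs_hz, mri_size = config$cohort$mri_size,
      seed = derive_seed(seed, "cohort"))
    simulate_cohort(cp)
  })
  n <- nrow(cohort$patients)

  say("stage 2/8: preprocess ECGs and volumes")
  prepped <- cache_stage(out_dir, "prep", resume = resume, expr = {
    beats <- lapply(cohort$ecg, prep_ecg)
    inputs <- lapply(cohort$mri, function(m) prep_mri(m, backend = "analytic"))
    list(beats = beats, inputs = inputs)
  })

  say("stage 3/8: development/external split")
  split_ids <- cache_stage(out_dir, "split", resume = resume, expr = {
    fold <- stratified_folds(cohort$patients$outcome, k = 3,
                             seed = derive_seed(seed, "split"))
    k_dev <- round(3 * config$split$dev_frac)
    dev <- which(fold <= k_dev)
    list(dev = dev, ext = setdiff(seq_len(n), dev))
  })
  dev <- split_ids$dev; ext <- split_ids$ext

  say("stage 4/8: train beta-VAEs on the development split")
  vaes <- cache_stage(out_dir, "vaes", resume = resume, expr = {
    L <- ncol(prepped$beats[[1]]$beats)
    cfg_e <- vae_config(modality = "ecg", input_shape = c(12L, L),
                        latent_dim = config$vae_ecg$latent_dim,
                        hidden = config$vae_ecg$hidden,
                        n_res = config$vae_ecg$n_res,
                        beta = config$vae_ecg$beta,
                        epochs = config$vae_ecg$epochs,
                        batch_size = config$vae_ecg$batch_size,
                        learning_rate = config$vae_ecg$learning_rate,
                        seed = derive_seed(seed, "vae_ecg"))
    cfg_m <- vae_config(modality = "mri",
                        latent_dim = config$vae_mri$latent_dim,
                        hidden = config$vae_mri$hidden,
                        n_res = config$vae_mri$n_res,
                        beta = config$vae_mri$beta,
                        epochs = config$vae_mri$epochs,
                        batch_size = config$vae_mri$batch_size,
                        learning_rate = config$vae_mri$learning_rate,
                        pool = config$vae_mri$pool,
                        seed = derive_seed(seed, "vae_mri"))
    list(ecg = train_vae(prepped$beats[dev], cfg_e),
         mri = train_vae(prepped$inputs[dev], cfg_m))
  })

  say("stage 5/8: extract latent features")
  latents <- cache_stage(out_dir, "latents", resume = resume, expr = {
    list(ecg = encode_cohort(vaes$ecg, prepped$beats, prefix = "ecg",
                             patient_id = cohort$patients$patient_id),
         mri = encode_cohort(vaes$mri, prepped$inputs, prefix = "mri",
                             patient_id = cohort$patients$patient_id))
  })

  say("stage 6/8: clinical processing and branch matrices")
  branches <- cache_stage(out_dir, "branches", resume = resume, expr = {
    clin_dev <- impute_missing(cohort$clinical[dev, ],
                               seed = derive_seed(seed, "impute_dev"))
    clin_ext <- impute_missing(cohort$clinical[ext, ][
      names(clin_dev)], seed = derive_seed(seed, "impute_ext"))
    enc <- fit_feature_encoder(clin_dev)
    Xc <- matrix(NA_real_, nrow = n,
                 ncol = ncol(apply_feature_encoder(enc, clin_dev)))
    Xc[dev, ] <- apply_feature_encoder(enc, clin_dev)
    Xc[ext, ] <- apply_feature_encoder(enc, clin_ext)
    colnames(Xc) <- colnames(apply_feature_encoder(enc, clin_dev))
    Xm <- as.matrix(latents$mri[-1])
    Xe <- as.matrix(latents$ecg[-1])
    list(multimodal = cbind(Xm, Xe, Xc), mri = Xm, ecg = Xe, clinical = Xc)
  })
  y <- cohort$patients$outcome

  say("stage 7/8: train branches and predict the external split")
  fitted <- cache_stage(out_dir, "models", resume = resume, expr = {
    lapply(rlang::set_names(names(branches)), function(br) {
      X <- branches[[br]]
      cfgm <- config$model
      if (isTRUE(config$tune$enabled)) {
        tuned <- tune_hyperparameters(
          X[dev, , drop = FALSE], y[dev], k_folds = config$tune$k_folds,
          n_trials = config$tune$n_trials,
          seed = derive_seed(seed, paste0("tune_", br)))
        cfgm <- tuned$best
      }
      train_classifier(X[dev, , drop = FALSE], y[dev], config = cfgm,
                       seed = derive_seed(seed, paste0("fit_", br)),
                       branch = br)
    })
  })
  predictions <- purrr::imap_dfr(fitted, function(m, br) {
    predict_risk(m, branches[[br]][ext, , drop = FALSE],
                 patient_id = cohort$patients$patient_id[ext]) |>
      dplyr::mutate(label = y[ext])
  }) |>
    dplyr::rename(score = "probability")

  say("stage 8/8: evaluate and explain")
  metrics <- evaluate_predictions(predictions, n_boot = config$evaluate$n_boot,
                                  seed = derive_seed(seed, "boot"))
  delong <- purrr::map_dfr(c("mri", "ecg", "clinical"), function(br) {
    a <- predictions[predictions$branch == "multimodal", ]
    b <- predictions[predictions$branch == br, ]
    dplyr::mutate(delong_test(a$score, b$score, a$label),
                  comparison = paste0("multimodal_vs_", br))
  })
  explain <- NULL
  if (isTRUE(config$explain$enabled)) {
    attr_mm <- shapley_attributions(fitted$multimodal,
                                    branches$multimodal[ext, , drop = FALSE])
    tl <- top_latents(attr_mm, m = config$explain$m_top)
    # global ranking: mean |phi| over the explained cohort, latents only
    mean_abs <- colMeans(abs(attr_mm$phi))
    mri_rank <- order(-mean_abs[grep("^mri_", names(mean_abs))])
    top_mri_latent <- mri_rank[1]
    trav <- latent_traversal(vaes$mri, latents$mri, top_mri_latent)
    att <- gradient_attention_map(
      vaes$mri, prepped$inputs[[ext[1]]],
      latent_indices = seq_len(min(config$explain$m_top,
                                   vaes$mri$config$latent_dim)))
    explain <- list(attributions = attr_mm, top_latents = tl,
                    traversal = trav, attention = att)
  }

  run <- structure(list(config = config, cohort = cohort$patients,
                        dev_ids = dev, ext_ids = ext,
                        vae_ecg = vaes$ecg, vae_mri = vaes$mri,
                        branches = branches,
                        models = fitted, predictions = predictions,
                        metrics = metrics, delong = delong, explain = explain),
                   class = "deeprisk_run")
  if (!is.null(out_dir)) {
    utils::write.csv(predictions, file.path(out_dir, "predictions.csv"),
                     row.names = FALSE)
    utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    write_run_manifest(run, out_dir)
  }
  run
}

write_run_manifest <- function(run, out_dir) {
  files <- list.files(out_dir, pattern = "\\.csv$", full.names = TRUE)
  digests <- vapply(files, function(f)
    as.character(tools::md5sum(f)), character(1))
  manifest <- list(
    package_version = as.character(utils::packageVersion("deeprisk")),
    timestamp = format(Sys.time(), tz = "UTC"),
    config = unclass(run$config),
    stage_seeds = lapply(
      rlang::set_names(c("cohort", "split", "vae_ecg", "vae_mri",
                         "impute_dev", "impute_ext", "boot")),
      function(s) derive_seed(run$config$seed, s)),
    file_digests = as.list(digests)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' @export
print.deeprisk_run <- function(x, ...) {
  cat(sprintf("<deeprisk_run> %d patients (%d development / %d external)\n",
              nrow(x$cohort), length(x$dev_ids), length(x$ext_ids)))
  aur <- x$metrics[x$metrics$metric == "auroc", ]
  for (i in seq_len(nrow(aur))) {
    cat(sprintf("  %-11s AUROC %.3f (95%% CI %.3f-%.3f)\n", aur$branch[i],
                aur$point[i], aur$lo[i], aur$hi[i]))
  }
  invisible(x)
}

#' @export
glance.deeprisk_run <- function(x, ...) {
  x$metrics |>
    dplyr::filter(.data$metric == "auroc") |>
    dplyr::select("branch", auroc = "point", "lo", "hi")
}
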