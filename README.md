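# deeprisk

Multimodal one-year ventricular-arrhythmia risk prediction for
non-ischaemic cardiomyopathy, as a reproducible R pipeline: synthetic
cohort generation (12-lead ECGs, LGE cardiac MRI, clinical tables,
outcomes with known planted effect sizes), signal/image preprocessing,
residual β-VAE representation learning, four gradient-boosted risk
branches (multimodal, MRI, ECG, clinical), a full evaluation stack, and
latent-space explainability.

Real cohorts of this kind are not redistributable, so the package is
built around a generator whose information content is known exactly:
every scientific property of the pipeline (signal recovery, branch
ordering, calibration, metric correctness) is tested against ground
truth or independent oracles. See `vignette("deeprisk-methods")` for
the model, numerical choices and their rationale.

## Worked example

A complete run — simulate, preprocess, train both VAEs, fit the four
branches, evaluate on the held-out external split — from one seed:

```r
library(deeprisk)

cfg <- pipeline_config(cohort = list(n_patients = 120), seed = 1)
run <- run_deeprisk_pipeline(cfg, out_dir = "run1", verbose = TRUE)
print(run)
#> <deeprisk_run> 120 patients (81 development / 39 external)
#>   multimodal  AUROC 0.738 (95% CI 0.535-0.891)
#>   mri         AUROC 0.590 (95% CI 0.398-0.757)
#>   ecg         AUROC 0.583 (95% CI 0.379-0.792)
#>   clinical    AUROC 0.630 (95% CI 0.421-0.787)
```

`run1/` now contains `predictions.csv`, `metrics.csv`, a stage cache,
and `manifest.json` (config snapshot, per-stage seeds, file digests);
re-running with the same config reproduces every number exactly.

Branch metrics with bootstrap intervals:

```r
glance(run)
#> # A tibble: 4 × 4
#>   branch     auroc    lo    hi
#>   <chr>      <dbl> <dbl> <dbl>
#> 1 multimodal 0.738 0.535 0.891
#> 2 mri        0.590 0.398 0.757
#> 3 ecg        0.583 0.379 0.792
#> 4 clinical   0.630 0.421 0.787
```

At this deliberately small demonstration size the external split has
only 39 patients, so intervals are wide. On a 600-patient cohort
(400 development / 200 external) with a strong planted lesion effect
and a latent-48 MRI VAE (the largest shipped configuration, ~7 min on
one CPU), the held-out branch AUROCs are:

| branch     | AUROC | 95% CI      |
|------------|-------|-------------|
| multimodal | 0.763 | 0.693–0.825 |
| MRI        | 0.808 | 0.745–0.862 |
| ECG        | 0.526 | 0.433–0.607 |
| clinical   | 0.566 | 0.477–0.649 |

(the generator here plants most of its signal in lesion burden, so the
MRI branch leads and the multimodal branch tracks it).

Explainability artefacts live on the run object:

```r
run$explain$top_latents[1:2, 1:3]   # per-patient latent rankings
autoplot(run$explain$traversal)      # decode a swept MRI latent
plot_attention_overlay(run$explain$attention,
                       prep_mri(simulate_lge_volume(mri_sim_params(seed = 1))))
```

Individual stages are ordinary functions if you want the pieces:
`simulate_cohort()`, `prep_ecg()`, `prep_mri()`, `train_vae()`,
`encode_cohort()`, `impute_missing()`, `train_classifier()`,
`evaluate_predictions()`, `shapley_attributions()`. A thin CLI wraps
them: `exec/deeprisk simulate|prep-ecg|prep-mri|evaluate|compare|run`.

## Reproduction

Unit, property and acceptance tests (the acceptance blocks verify
metric/ELBO/Shapley identities against independent oracles, DeLong null
calibration, bootstrap coverage, end-to-end signal recovery and branch
ordering on the synthetic generator):

```r
testthat::test_dir("tests/testthat", package = "deeprisk",
                   load_package = "installed")
```

Headline quantities from a fresh end-to-end run, written as a flat JSON
report:

```sh
Rscript scripts/acceptance.R --seed 1 --out acceptance.json
```

Both are deterministic given the seed and run on a single CPU.
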