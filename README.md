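# painprint

Serum MALDI-TOF fingerprint classification for pathological-pain model
cohorts.

Chronic-pain research lacks objective biomarkers. One candidate read-out
is the serum *fingerprint*: the whole pattern of a MALDI-TOF mass
spectrum (relative intensity vs m/z, positive linear mode, 0–10,000 Da),
classified as a multivariate pattern instead of being reduced to single
metabolites. `painprint` implements that workflow as a tested R
pipeline:

- **Preprocessing** — Savitzky–Golay smoothing, robust loess baseline
  subtraction, normalization to a 100% base peak, rigid m/z alignment,
  SNR-based peak detection, triplicate merging (majority rule), and
  matrix-blank exclusion.
- **Features** — cross-sample peak binning; variance filter keeping
  m/z columns with s² > 1 (strict, raw scale); Z-scaling with stored
  fold parameters; PCA diagnostics; optional fusion of behavioral
  endpoints (PTD = plantar-test latency, VFD = von Frey threshold).
- **Behavior** — Hargreaves mean withdrawal latency with the 25 s
  cut-off, and the von Frey up-down 50% threshold by the Dixon formula
  threshold(g) = 10^(Xf + κδ)/10,000, with κ obtained by maximum
  likelihood from the response pattern (user-replaceable table).
- **Classifier** — a multilayer perceptron (3 logistic hidden units,
  backpropagation, 50,000-iteration cap) with a confidence-0.05 reject
  rule: a sample is assigned a class only when that class's activation
  is ≥ 0.95 and all others are ≤ 0.05, otherwise it is `unknown`, which
  counts as an error. Validation is leave-one-out with the variance
  filter, scaling and network re-fit on every fold.
- **Synthetic cohorts** — a seeded generator with known ground truth
  (class-dependent peaks concentrated below 1,000 Da, matrix peaks,
  baseline, noise, calibration jitter, triplicates, behavioral latents),
  so the full pipeline is testable without instrument data.

## Worked example

Simulate a two-group cohort (15 animals per group, triplicate spots),
preprocess, build features, fuse behavior, and cross-validate:

```r
library(painprint)

cfg <- run_config(name = "demo",
                  out_dir = "demo_run",
                  cohort = cohort_config(groups = c("control", "model"),
                                         n_per_group = 15),
                  seed = 1)
res <- run_experiment(cfg)
res$summary
```

```
      variant n_features success_percentage n_unknown
1         MSD         76                100         0
2     MSD+PTD         77                100         0
3     MSD+VFD         77                100         0
4 MSD+PTD+VFD         78                100         0
```

Each row is one fusion variant: `n_features` is the number of columns
that survived the s² > 1 filter (plus fused behavioral columns), and
`success_percentage` is leave-one-out success with `unknown` counted as
an error. A per-variant report:

```r
classification_report(res$cv$MSD)
```

```
Samples: 30
Overall success: 100.0% (100%)
Unknown (rejected, counted as errors): 0
  control       15/ 15 correct (100.0%), 0 unknown
  model         15/ 15 correct (100.0%), 0 unknown
```

The run directory also receives the raw binned feature matrix, PCA
scores, per-sample predictions for every variant and a provenance record
(config echo, master seed, package version). Reruns with the same seed
are byte-identical.

Lower-level entry points (`generate_cohort`, `preprocess_cohort`,
`bin_peaks`, `variance_filter`, `z_scale`, `fuse_behavior`, `loocv`,
`mean_withdrawal_latency`, `updown_50pct_threshold`, `simulate_updown`,
`read_spectrum`/`write_spectrum` for delimited text and minimal mzML)
are documented individually.

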