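# pshg

Analysis of widefield polarimetric second-harmonic generation (P-SHG)
microscopy images of collagenous tissue, from raw polarization-state
intensity stacks to tissue classification.

Fibrillar collagen is non-centrosymmetric and frequency-doubles incident
laser light; imaging that SHG signal under varying incident and analyzed
polarization states reveals the ultrastructure of the extracellular matrix,
which is remodeled in tumors. This package is written for microscopists and
image analysts who acquire such 16-state widefield stacks (4 generator x 4
analyzer states: LCP, HLP, RCP, VLP on each side) and want the full
downstream analysis: per-pixel polarimetric parameter maps, sub-image
texture statistics, nonparametric group comparison, and a cross-validated
logistic-regression tissue classifier. Because raw tissue-microarray data
are rarely shareable, the package also ships a physics-based synthetic
collagen-fiber simulator that provides ground truth for every stage.

## The model

For each incident (PSG) state the emitted SHG is described by a reduced
Stokes vector, reconstructed per pixel from the four analyzed intensities:

    s0 = (I_HLP + I_VLP + I_RCP + I_LCP) / 2
    s1 = I_HLP - I_VLP
    s3 = I_RCP - I_LCP

(s2 is not measured by this scheme). Five parameter maps follow:

* **ICP** — circular-input SHG intensity, `(s0^RCP + s0^LCP)/2`,
  independent of in-plane fiber orientation;
* **R-ratio** — the achiral susceptibility ratio `chi_zzz / chi_zxx`
  (z along the fiber axis), solving
  `R = 1 + 2A ± 2*sqrt(A^2 - 1)` with
  `A = (s0^RCP + s0^LCP)/(s3^RCP - s3^LCP)`; the branch is calibrated by a
  forward-model round trip (collagen occupies the minus-root regime R < 3);
* **DCP** — degree of circular polarization,
  `(|s3^RCP|/s0^RCP + |s3^LCP|/s0^LCP)/2`;
* **SHG-CD / SHG-LD** — circular / linear dichroism,
  `2(s0^RCP - s0^LCP)/(s0^RCP + s0^LCP)` and
  `2(s0^VLP - s0^HLP)/(s0^VLP + s0^HLP)`, both in [-2, 2], proxies for
  out-of-plane and in-plane fiber orientation.

Each map is tiled into sub-images (64 per core by default); per tile and
parameter the pipeline computes the mean, the mean absolute deviation, and
five grey-level co-occurrence (Haralick) texture features — contrast,
correlation, entropy, angular second moment, inverse difference moment —
over a background-masked, direction-averaged GLCM, plus the pixel density
(count of above-SNR pixels), for 36 features per sub-image. Features with
no significant normal-vs-tumor difference (Kruskal-Wallis + Dunn-Bonferroni
after 1st-99th percentile trimming) are excluded; the rest feed a binary
logistic regression evaluated by repeated stratified five-fold
cross-validation at a 50% posterior threshold, reporting accuracy, F1,
TPR/TNR/PPV/NPV and their complements, AUROC and Brier score as
mean ± SD across repeats.

## Worked example

A complete synthetic study — simulate labelled cores, reconstruct, mask,
extract features, screen, classify:

```r
library(pshg)
cfg <- pshg_config(n_per_group = 4, core_size = 256, repeats = 20, seed = 42)
run <- run_pipeline(cfg, out_dir = "pshg_demo")
print(run)
#> P-SHG pipeline run
#>   cores: 8, feature rows: 482, predictors: 33 (excluded: 3)
#> Logistic regression, 5-fold stratified CV x 20 repeats (threshold 0.50)
#>   accuracy 0.994 +/- 0.002
#>   f1       0.994 +/- 0.002
#>   auroc    0.996 +/- 0.002
#>   brier    0.005 +/- 0.002
#> Held-out prediction: 119 tiles from 2 cores
#>   accuracy 0.992, F1 0.991, AUROC 0.998, Brier 0.008
```

Eight synthetic cores (4 normal, 4 tumor) produce 482 viable sub-images;
3 of the 36 features show no significant normal-vs-tumor difference at this
sample size and are excluded, leaving 33 predictors. The CV panel says the
two groups are almost perfectly separable (accuracy 99.4 ± 0.2%), and the
two cores held out of training entirely are predicted tile-by-tile with
99.2% accuracy — the synthetic presets encode strong, clean contrasts
(tumor: sparser, dimmer, straighter fibers with higher R), so near-perfect
separation is the expected behaviour, not a claim about real tissue.
Artifacts (feature CSV, significance records, exclusion list, metrics and
run log as JSON) land in `pshg_demo/`.

Lower-level entry points: `simulate_stack()` / `generate_dataset()`,
`read_stack()` / `write_stack()` (16-bit TIFF stacks, multi-page or one
file per state), `reconstruct_stokes()`, `compute_parameter_maps()`,
`build_feature_table()`, `significance_matrix()`, `fit_logistic_cv()`,
`predict_held_out()`, `subdivision_sweep()`.

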