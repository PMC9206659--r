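---
title: "Widefield P-SHG tissue analysis: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Widefield P-SHG tissue analysis: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pshg)
```

This vignette documents the science inside the package: the measurement
model, the polarimetric parameter definitions, the masked texture
statistics, the statistical screen, the classification protocol, and — in
some detail — the forward model behind the synthetic-data generator and
the design decisions taken where more than one reasonable convention
exists.

## The measurement and its reduced Stokes reconstruction

A widefield P-SHG instrument prepares four incident polarization states
with a variable retarder (LCP, HLP, RCP, VLP at quarter-, half-,
three-quarter- and full-wave retardance) and analyzes the emitted SHG with
the same four states, giving the 16 intensity images of
`measurement_scheme()`. For each incident state, a four-state analyzer
determines three elements of the emitted Stokes vector:

* `s0 = (I_H + I_V + I_R + I_L) / 2`
* `s1 = I_H - I_V`
* `s3 = I_R - I_L`

`s2` would require diagonal linear analyzer states and is not measured.
Two estimates of `s0` exist (`I_H + I_V` and `I_R + I_L`); the package
averages them, which halves the variance of `s0`, and reports the absolute
difference between them per pixel as a consistency residual — on
noise-free synthetic data it is zero to machine precision, so any
structure in it on real data measures co-registration or polarization
error. Which overall sign `s1` and `s3` carry depends on instrument
conventions that cannot be recovered from intensity data alone;
`reconstruct_stokes(sign_s1 =, sign_s3 =)` exposes both flips, and all
sign-sensitive behaviour in the package (the R-ratio branch, the
dichroism signs) is made consistent with the simulator's conventions,
which are documented in code.

## Polarimetric parameters

**ICP** averages `s0` over the two circular incident states. Circular
input has no in-plane axis, so ICP is invariant under in-plane fiber
rotation (a property test verifies this to 1e-9 on noise-free fields).

**R-ratio.** With `A = (s0^RCP + s0^LCP) / (s3^RCP - s3^LCP)`, the
susceptibility ratio solves the quadratic `(R-1)^2 - 4A(R-1) + 4 = 0`,

```
R = 1 + 2A ± 2*sqrt(A^2 - 1),
```

whose two roots satisfy `(R+ - 1)(R- - 1) = 4`: they are images of each
other on either side of `R = 3`. A formula alone therefore cannot decide
the branch; the package calibrates it (`branch = "auto"`) by simulating a
tiny noise-free single fiber with a known ratio in the collagen regime
(`calibration_r0 = 2` by default), reconstructing it, and keeping the root
that returns the truth — the minus root under the package's conventions.
Pixels with `|A| < 1` have no real root; they indicate depolarization or
noise outside the single-fiber model and are marked invalid rather than
clamped. `compute_r_ratio()` records the selected branch as an attribute
and the pipeline log carries it.

**DCP** is the mean of `|s3|/s0` over the two circular inputs. Noise can
push it above 1; since it is a polarized-to-total ratio, such pixels are
clamped to 1 and counted in the QC block. Note that single-fiber emission
is fully *polarized* yet generally elliptical, so DCP < 1 even for perfect
fibers; DCP only reaches 1 where the emitted light is purely circular.

**SHG-CD and SHG-LD** are normalized intensity differences between the
two circular and the two linear incident states, bounded by ±2 with the
bound attained exactly when one of the two states produces no signal.

**SNR masking.** The instrument does not measure noise, so the package
defines SNR as a background-referenced z-score, with background statistics
supplied explicitly or estimated from a user-designated background
rectangle. The analysis threshold defaults to 3 (display conventionally
uses 1). Pixels below threshold become NaN in every parameter map, and all
downstream statistics skip NaN — this is the single missing-data
convention of the whole pipeline.

## Masked texture features

Each parameter map is quantized to `n_g` grey levels (default 64 for
full-scale analysis; the bundled pipeline default is 32, which on 64 px
tiles keeps co-occurrence matrices well filled) over a robust per-core
range (1st–99th percentile of valid pixels), then tiled, and each tile's
grey-level co-occurrence matrix is built at offset `d = 1` along 0, 45, 90
and 135 degrees. Pairs touching a NaN pixel are skipped, each pair is
counted in both orders (symmetric GLCM), per-angle count matrices are
averaged, and the result is normalized to a pair-probability matrix. From
it: contrast, correlation, entropy (bits), angular second moment, inverse
difference moment. A uniform tile gives ASM = IDM = 1 and
contrast = entropy = 0, and its correlation is undefined (zero marginal
variance, reported NA). Correlation is implemented with the standard
Haralick sign, under which +1 means perfectly positively correlated
neighbours; a `legacy_sign` flag restores the negated variant seen in some
writeups whose verbal range description contradicts their printed formula.
The marginal mean and SD entering correlation come from the GLCM marginal
distribution, which for a symmetric GLCM is the same along rows and
columns.

The implementation is validated against a brute-force pair-enumeration
oracle on a thousand random masked tiles (exact probability agreement),
and the four-angle average is checked to be invariant under tile rotation.

Per tile and parameter the table also carries the mean and the mean
absolute deviation about the mean over valid pixels, plus the tile's pixel
density (count of valid pixels). That makes 5 parameters x 7 statistics
+ pixel density = 36 features. Tiles with fewer than 1% valid pixels
(configurable) are deemed non-viable and dropped — an explicit, logged
stand-in for the manual discarding of empty corner regions that a human
analyst would perform; an optional ROI mask serves the same purpose.

## Statistical screen

Feature values are compared across groups with the Kruskal-Wallis H test
(tie-corrected, `k - 1` degrees of freedom) followed by Dunn's pairwise
z-tests on mean ranks with Bonferroni adjustment over the pairs within
each feature, each feature tested separately. Adjusted p < 0.001 counts as
highly significant, p < 0.05 as significant. Before testing, each group's
values are trimmed at the 1st and 99th percentiles (type-7 interpolated
quantiles; because the bounds are recomputed from whatever data they are
applied to, trimming is applied once, to raw values). Features with no
significant difference between the normal group and any other group are
excluded from classification. Trimming is applied in the testing stage
only — whether to trim before classification as well is exposed as a
choice for the caller rather than silently imposed. A Shapiro-Wilk /
per-group normality report is provided purely as documentation for the
nonparametric choice; it gates nothing.

The type-I error of the Dunn-Bonferroni path is verified by simulation:
under the null at two groups of 200, the rejection rate at 0.05 sits
within 0.05 ± 0.02 over a thousand replicates.

## Classification protocol

A binary logistic regression (plain maximum likelihood; an optional ridge
penalty via `glmnet` exists for separable data) is evaluated by repeated
stratified five-fold cross-validation. Per repeat, a fresh stratified
partition is drawn; per fold, features are standardized using
training-fold statistics only; out-of-fold posterior probabilities are
pooled within the repeat and the full metric panel is computed at the 50%
threshold. Pooling per repeat (rather than per fold) yields one metric
sample per repeat, so the SD across repeats measures protocol stability.
Stratification is by class label; treating each sub-image as an
independent data point is the protocol's own assumption, and grouping all
tiles of a core into one fold is left to the caller via
`predict_held_out()`, which implements the stricter core-level holdout:
remove whole cores, refit on the rest, predict their tiles (with a
leakage guard on core ids). AUROC uses midranks (ties count one half) and
is checked against an independent implementation; Brier is the mean
squared probability error. `subdivision_sweep()` re-runs the protocol at
several tiles-per-side levels: coarser subdivisions give fewer, larger
samples — often slightly higher point metrics with visibly larger SD,
which is why 64 sub-images per core is the default operating point.

## The synthetic-data generator

The generator exists so that every stage has a ground-truth oracle. It is
a *forward model*, not a tissue emulator:

1. **Geometry.** Fibers are random-walk polylines with per-step heading
   increments of SD `orientation_dispersion / sqrt(L)` (so the heading
   spread over a fiber's length L matches the preset), dilated to a random
   2–6 px width; painted pixels record the local tangent as in-plane
   orientation delta. Out-of-plane tilt alpha, ratio R and amplitude are
   drawn per fiber. Painting stops within ±10% of the target fiber
   density. Overlaps keep the first fiber (fields stay single-valued);
   incoherent summation of several fields is available separately for
   studying depolarization.
2. **Emission.** Per pixel, the incident Jones field is projected onto the
   fiber frame and a cylindrically symmetric, Kleinman-restricted second-
   order susceptibility with one chiral element produces
   `Pz = (Ex^2 + Ey^2) + R Ez^2`, `Px = 2 Ex Ez + 2 c Ey Ez`,
   `Py = 2 Ey Ez - 2 c Ex Ez` (fiber frame, `chi_zxx = 1`). The transverse
   lab-frame components of P form the outgoing Stokes vector. The chiral
   coefficient `c` is complex: its phase is the retardance between chiral
   and achiral components, and with a purely real `c` the circular
   dichroism of tilted fibers vanishes identically — the chiral term then
   sits in quadrature and cancels from both circular intensities. The
   presets default to a 90 degree phase (quadrature), which maximizes
   SHG-CD at given `|c|`.
3. **Detection.** A perfect analyzer projects the Stokes vector
   (`I = (s0 + shat . s)/2`), then optional Poisson shot noise on the
   signal and Gaussian dark background are added. The preset amplitudes
   (normal 100, tumor 40 counts-scale) against a background of
   mean 10, SD 2 put fiber-pixel SNR in the tens, comfortably above the
   analysis threshold of 3.

**What the presets encode.** Only the *directions* of the tissue
contrasts: tumor has lower fiber density (0.15 vs 0.35), lower amplitude,
higher R (2.1 ± 0.12 vs 1.6 ± 0.10, inside the 1.4–2.4 range collagen
occupies), and straighter fibers (orientation dispersion 10 vs 30
degrees, which narrows the dichroism spreads). The magnitudes are
simulator choices made once for plausibility, not fits to any dataset.
Consequently, passing the end-to-end discrimination test shows the
*pipeline* preserves and recovers these contrasts — it says nothing about
effect sizes, morphology, birefringence, scattering, focal-volume
averaging or staining artifacts in real tissue, all of which the model
omits.

**Model-level checks** (all property tests): emission is fully polarized
(`s0^2 = s1^2 + s2^2 + s3^2`); in-plane fibers show zero SHG-CD for any
chirality; flipping the sign of `c` or of alpha mirrors the SHG-CD map;
rotating the field by 90 degrees while swapping HLP and VLP leaves linear
intensities invariant; the apparent R of tilted fibers increases
monotonically with tilt under this projection model (the direction is
recorded by the test rather than asserted from theory, since the
projection model fixes it only empirically).

## Numerical and formatting choices

* Degenerate inputs: all-NaN tiles yield NA features; single-level GLCMs
  yield NA correlation; zero-denominator pixels in any ratio map are NaN;
  `|A| < 1` pixels are invalid, not clamped; DCP is the only clamped
  quantity (at 1, counted).
* Quantization clips at the range ends, so extreme pixels fall into the
  first/last grey level rather than distorting the binning.
* Percentiles everywhere are type-7 (linear interpolation).
* Seeds: every stochastic routine takes an explicit seed; nested
  operations derive child seeds deterministically below 2^31, and RNG
  state is restored after use, so library calls never perturb a caller's
  stream.
* TIFF storage: intensity stacks are written as 16-bit integer TIFF with a
  JSON sidecar (counts per grey level), the native format of scientific
  cameras; parameter maps are scaled 32-bit TIFFs with grey level 0
  reserved for NaN plus a validity-mask image, because the available TIFF
  writer has no IEEE-float sample format. Round trips restore NaN exactly
  and values to 32-bit quantization.
* Default problem sizes in the bundled tests and pipeline (cores of
  256–512 px, 4–8 per group, 20 CV repeats) are chosen so a full run
  completes in minutes on one CPU while leaving every statistical
  conclusion comfortably inside its tolerance; the full-scale protocol
  (2048 px cores, 1000 repeats) is a configuration change, not a code
  change.

## Known limitations

* The forward model is single-fiber-per-pixel and noise-free in
  polarization: DCP on synthetic data is mostly near 1 and carries less
  information than in scattering tissue.
* The reduced reconstruction assumes ideal, co-registered analyzer
  states; real LCVR imperfections would enter as `s0` consistency
  residuals and sign-convention errors, which the package surfaces but
  does not correct.
* The R-ratio branch calibration assumes the sample occupies one side of
  `R = 3`; samples straddling it are fundamentally ambiguous in this
  reduced scheme.
* Group presets are qualitative; absolute metric values on synthetic data
  (e.g. near-perfect accuracy) reflect the presets' clean separation and
  must not be read as expected clinical performance.
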