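---
title: "Methods: stain-free IR spectral histopathology with spectrohist"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stain-free IR spectral histopathology with spectrohist}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem and the model

Infrared microspectroscopy yields a hyperspectral cube: an image in which
every pixel carries an absorbance spectrum over the mid-IR range
(3850–900 cm⁻¹ here). Different tissue constituents absorb at
characteristic wavenumbers — protein backbone vibrations in the Amide I
(1762–1585 cm⁻¹), Amide II (1585–1473 cm⁻¹) and Amide A+B
(3600–3000 cm⁻¹) bands, collagen prolines near 1337 cm⁻¹, C–C/C–OH
carbohydrate modes around 1160 cm⁻¹, nucleic-acid phosphate stretches near
1080 cm⁻¹ — so a pixel's spectrum is a biochemical fingerprint of the
tissue under it. `spectrohist` classifies each pixel of a pancreatic
tissue section into seven histological classes (benign epithelium, cancer,
PanIN, inflammation, fiber, blood, necrosis) and aggregates the pixel
calls into a tissue-level healthy/pathological screening decision.

The pipeline is: MNF denoising → region-local rubber-band baseline
correction → band metrics normalized to Amide I → random-forest
classification → leave-one-mouse-out (LOMO) validation → majority
filtering → pathology-pixel-count ROC.

# Synthetic phantoms: what they emulate, and what they do not

Real measurements of this kind come from mouse cohorts (controls plus KC
and KPC genotypes, which develop PanIN and PanIN→cancer respectively).
The phantom generator (`make_phantom()`, `make_cohort()`) replaces them
with cubes that reproduce the statistical structure the analysis depends
on:

* **Class spectra** are sums of Gaussian bands at the standard mid-IR
  assignments, with amplitudes differing where real classes differ (fiber
  rich in collagen bands, cancer/PanIN elevated in DNA/RNA and
  carbohydrate bands, blood protein-dominated, necrosis protein-depleted),
  over a low-order polynomial drift. The amplitudes are surrogates chosen
  for plausible separability, not fits to measured mean spectra, which are
  published only graphically.
* **Spatial layout**: classes occupy contiguous blobs grown by seeded
  dilation, mimicking histological coherence. Contiguity matters because
  edge exclusion and majority filtering assume spatially coherent labels.
* **Thickness ("size") effects**: a smooth multiplicative per-pixel field
  in [0.6, 1.4] scales each spectrum, exactly the nuisance the Amide I
  normalization must remove.
* **Noise**: white noise (σ = 0.01 absorbance) plus spatially correlated
  noise (σ = 0.005, Gaussian correlation length 2 px, realized by kernel
  smoothing of white noise) — the latter gives the MNF a removable
  low-SNR structure.
* **Mouse batch effects**: each mouse perturbs every band amplitude by a
  log-normal factor (σ = 0.05), which makes leave-one-mouse-out strictly
  harder than random pixel splits.
* **Background** pixels get a flat 0.02-absorbance spectrum plus noise and
  are excluded by the tissue mask.

Defaults follow the measurement geometry of the instrument class being
emulated: 64 × 64-pixel tiles (a focal-plane-array detector), 3850–900
cm⁻¹ at 4 cm⁻¹ point spacing (an 8 cm⁻¹ spectral resolution instrument
with zero-filling halves the point spacing), 19-mouse cohorts split
6 control / 7 KC / 6 KPC.

The phantoms deliberately omit physics that the pipeline does not model:
Mie and resonant-Mie scattering, transflection standing-wave artifacts,
water-vapor lines, and detector nonlinearity. Consequently, passing
end-to-end tests demonstrates that the pipeline recovers structure *of the
kind it assumes*; it does not certify performance on real transflection
measurements, whose uncorrected scattering near tissue edges is precisely
why edge pixels are excluded from training and validation.

# Numerical choices

**Noise covariance estimation.** The MNF needs a noise covariance. It is
estimated per cube from horizontally and vertically adjacent in-mask pixel
pairs: the covariance of difference spectra divided by 2, which recovers
the per-band noise covariance when the signal varies slowly. Differences
taken across a class boundary carry signal, not noise, and would dominate
the estimate, so pairs whose difference norm exceeds
(1 + 8/√(2B)) × median norm are discarded: for B bands the norm of a pure
noise difference concentrates around its median with relative spread
~1/√(2B), so the cut sits far outside the noise distribution at realistic
band counts while loosening automatically at small B, where a fixed
multiple would bias high-variance bands downward.

**Whitening and the ridge.** The generalized eigenproblem is solved by
symmetric whitening of the noise covariance with a ridge of
10⁻¹⁰ · trace/B added first, because phantom noise covariances can be
numerically singular. Components are ordered by decreasing whitened data
variance (signal-to-noise), and `forward`/`inverse` are exact inverses of
each other to ~10⁻¹² — at k = B denoising is the identity.

**Choice of k.** The default k = 20 retained components reflects the
reconstruction optimum of the emulated pipeline. On noisy cubes the
error-versus-k curve is U-shaped: too few components underfit the class
spectra, too many re-admit noise, and full rank returns the input. The
test suite pins exactly this shape rather than naive monotonicity.

**Rubber-band baseline.** The baseline of a segment is the lower convex
hull of its (wavenumber, absorbance) points, interpolated linearly between
hull vertices and anchored at both endpoints (computed by monotone-chain
in compiled code; verified exactly against a brute-force O(m³)
supporting-line construction). Corrected values are clamped at zero.

**Degenerate center of gravity.** A segment whose corrected mass is
indistinguishable from interpolation round-off (ΣA ≤ 10⁻¹² · m ·
(max|y| + 1)) has no meaningful cog; the region midpoint is returned so
feature rows stay finite, and such pixels remain usable.

**Amide I normalization of cog.** All three metrics, including the center
of gravity, are divided by the corresponding Amide I metric. Dividing a
band position by another band position is unusual — it turns cm⁻¹ into a
dimensionless ratio rather than leaving positions absolute — but it
follows the rule that *all* metrics are normalized; `normalize_cog =
FALSE` switches to absolute positions. Under this rule the entire feature
table is exactly invariant to uniform scaling of a pixel's spectrum, which
the tests verify end to end through MNF.

**Default region table.** The exact published 42-interval table lives in
supplementary material that is not machine-readable here, so the shipped
default is a documented surrogate: the named biology-bearing regions
(Amide A+B, Amide I, Amide II, collagen 1346–1325, carbohydrate
1180–1140, DNA/RNA 1180–980, lipid CH 3000–2800) plus contiguous tiles
over the fingerprint (1473–900, 30 tiles) and CH-stretch (3000–2800,
5 tiles) ranges, totalling 42 rows so the feature arithmetic
(3 × 41 = 123) is preserved. Any table with exactly one Amide I row
replaces it via `read_region_table()`. Regions are closed intervals on an
ascending axis; overlapping regions are legal.

**Training balance.** The forests train on per-class downsampled pixels
(to the smallest class in the fold, capped at 300 per class, seeded) —
the published procedure subsamples training pixels from annotated regions
without giving counts, and balancing keeps the minority neoplastic
classes from being swamped. Tree hyperparameters beyond the tree count
(50 detailed / 25 rapid / 100 importance) use the `randomForest`
defaults, pinned by the stored seed.

**Rapid class map.** The rapid screening model trains on
benign → benign, fiber → fiber, cancer and PanIN → pathology; blood,
inflammation and necrosis are excluded from rapid training (the screening
task contrasts exactly pathology/fiber/benign), and the exclusion count
is recorded on the fitted model.

**Chosen metric count.** The sweep formalizes "best performance at low
feature count" as: the smallest k whose LOMO accuracy is within 0.5
accuracy points (0.005) of the curve's maximum. On highly separable
phantoms this chooses small k; on real tissue the same rule lands at
larger counts.

**Tissue ROC.** A mouse is called pathological iff its majority-filtered
pathology pixel count exceeds the threshold; the sweep over all distinct
counts (plus both ends) traces the ROC, whose trapezoidal area equals the
Mann–Whitney U/(n₁n₂) with half-credit ties (verified exhaustively for
small cohorts). The operating threshold is the maximum count among
control (healthy) mice. The AUC standard error uses the Hanley–McNeil
formula with Q₁ = A/(2−A), Q₂ = 2A²/(1+A) — the standard diagnostic
choice, isolated in `auc_se()` so it can be swapped.

**Majority filter.** 5 × 5 modal filtering; background neither votes nor
is overwritten; ties keep the center label. Pooling of confusion counts
across LOMO folds is used for the reported matrices (per-fold matrices
are also returned), since fold-wise averaging would weight mice by
their pixel counts inconsistently.

# Problem sizes

The shipped tests and the acceptance script run entirely on synthetic
cohorts sized for a desk machine: 64 × 64 cubes at 4 cm⁻¹ spacing (739
bands) for the 19-mouse end-to-end evaluation, and 24 × 24 cubes at
12 cm⁻¹ spacing for the MNF property suites — the latter because
covariance estimation needs clearly more pixels than bands to be well
conditioned, a constraint worth remembering when applying MNF to small
crops of real data.

# Known limitations

* Phantom band amplitudes are surrogates; absolute accuracies and AUCs on
  phantoms characterize the pipeline's recovery of its own assumed
  structure, not expected performance on tissue.
* No scattering correction is implemented (matching the emulated
  pipeline); transflection edge artifacts are mitigated only by edge
  exclusion.
* The default region table is a surrogate for the published interval set;
  the specific six-metric selection of the published rapid model depends
  on that set and is therefore not reproduced, only the selection
  *procedure* is.
* ENVI (.hdr/.dat) is the canonical on-disk container; HDF5 is not read
  in this build.
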