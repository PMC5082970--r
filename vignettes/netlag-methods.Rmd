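---
title: "Methods: lagged inter-network connectivity analysis on synthetic BOLD cohorts"
author: "netlag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lagged inter-network connectivity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the models and
procedures it implements, the parameters that matter and their defaults,
what the synthetic cohort generator does and does not emulate, and the
numerical choices made where the design was genuinely open. Nothing here
states an empirical result that the test suite or `scripts/acceptance.R`
does not itself compute.

## 1. The analysis pipeline

`netlag` implements a resting-state functional-connectivity analysis for a
three-group clinical design (healthy controls HC, heterozygous HET and
homozygous HOM mutation carriers, default sizes 22/12/8):

1. **Preprocessing** (post-registration): discard the first 4 frames of
   each run (T1 equilibration), zero-phase band-pass 0.01–0.08 Hz, 3-D
   Gaussian smoothing at 8 mm FWHM. Head-motion realignment, slice timing
   and spatial normalization are upstream registration steps outside the
   package's scope; synthetic data are generated on a common grid, and
   requesting these steps logs a warning and does nothing.
2. **Group spatial ICA**: subject-level PCA (default 30 components of the
   216-frame runs), temporal concatenation, group PCA to the model order
   (20, user-set — no MDL/AIC order estimation), fixed-point ICA on the
   whitened spatial data, back-reconstruction of subject maps and time
   courses, z-scoring of maps, and template matching to name the five
   networks of interest (DMN, SN, ExN, rFP, lFP).
3. **Intra-network statistics**: voxelwise OLS on subject-specific maps
   with group as the factor of interest and grey-matter volume and
   education as nuisance covariates; cluster-level familywise error by
   Freedman–Lane permutation of maximal cluster size; a separate model with
   group-specific Corsi-span slopes (grey-matter volume and mutated gene as
   nuisance) for the brain–behaviour analysis within carriers.
4. **Inter-network statistics**: detrended network time courses, the
   constrained maximal lagged correlation per pair and subject, Fisher z,
   group ANCOVA per pair with Bonferroni correction over the pairs tested,
   covariate-adjusted pairwise contrasts, partial correlation of z with
   cognitive scores, and an uncorrected LEDD sensitivity check in the
   treated (HOM) group.

## 2. The constrained maximal lagged correlation

For detrended series $x, y$ of length $T$ the circular lagged correlation is
$r(\ell) = \mathrm{cor}(x_t, y_{(t+\ell) \bmod T})$; all $T$ samples enter
at every lag, there is no truncation. The statistic scans
$\ell \in [-12, 12]$ (25 lags; the "constraint" is exactly this bound) and
selects the lag with the best p value, which for fixed $T$ is the lag
maximizing $|r|$. Tie-break, needed only for constructed inputs: smaller
$|\ell|$ first, then the negative lag. The parametric p uses the t transform
of $r$ with $T-2$ degrees of freedom.

Two deliberate additions:

* Because maximizing $|r|$ over 25 lags inflates the naive p, the function
  can also report a **rotation-calibrated p**: the full circular correlation
  function is computed by FFT and the null distribution of the windowed
  maximum is read off circular rotations of one series, which preserves both
  series' autocorrelation. The naive p remains the primary output (it is
  what the downstream group analysis historically used); the rotation p is a
  calibration aid.
* At a numerically perfect $|r| = 1$ (constructed shifts) the Fisher
  transform is clamped at $1 - 10^{-15}$ so `z` stays finite.

Per-subject optimal lags are integers; group tables report their plain mean
(fractional), which is the only reading compatible with fractional group
mean lags. Group mean `r` is the arithmetic mean of per-subject selected
`r`; the group-level p in the pair-by-group table is a one-sample t test of
the group's z values against zero.

The Bonferroni scope is the number of pairs actually tested in the run —
$\binom{5}{2} = 10$ in the default design — never a hard-coded constant.

## 3. Group ICA details

* **Two-stage reduction.** Each run (frames x voxels, voxel means removed)
  is reduced to its top $k_1 = 30$ temporal principal components (or $T$ if
  smaller); the concatenated scores are reduced again to the model order
  $k_2 = 20$ by a second PCA.
* **Fixed-point ICA.** Symmetric FastICA with the tanh (logcosh) contrast,
  tolerance $10^{-6}$, at most 500 iterations. The symmetric update can fall
  into a period-2 cycle (two components of similar non-Gaussianity swapping);
  when a large step persists past iteration 50 the update is damped by
  averaging with the previous unmixing matrix and re-orthogonalizing, which
  collapses the cycle. Up to six deterministic restarts (seeds derived from
  the master seed) are attempted before the fit fails with the iteration
  count and final step size.
* **Sign convention.** Each component's sign is fixed so its spatial map has
  positive skewness — resting-state networks are sparse positive
  activations.
* **Back-reconstruction.** Subject maps are recovered by projecting the
  subject's reduced data through its block of the stacked mixing matrix
  (pseudo-inverse), subject time courses as `basis %*% mixing-block` — the
  classical two-stage-PCA back-reconstruction. Subject time courses are
  variance-normalized before the inter-network stage; Pearson correlations
  are scale-free, so this only standardizes downstream bookkeeping.
* **Template matching.** Spatial correlation of every z-scored group map
  with every template, then the exact maximum-sum injective assignment via a
  bitmask dynamic program (5 networks x 20 components is trivial for exact
  search). Ties resolve to the lower component index; any network matched
  below r = 0.3 flags the assignment for review — the automated stand-in for
  visual component review, with the match-r audit trail retained.

When recovery of known sources is quantified (tests, acceptance script), a
component map is compared against the **smoothing-matched** ground truth:
the pipeline smooths the data at 8 mm, so components estimate the smoothed
sources, and correlating against the unsmoothed map is geometrically capped
near $\bigl(2\sigma_1\sigma_2/(\sigma_1^2+\sigma_2^2)\bigr)^{3/2} \approx
0.95$ for the default blob width even for a perfect estimate.

## 4. Voxelwise statistics and cluster inference

The voxelwise GLM is ordinary least squares per voxel with t or F contrast
maps. Cluster-forming threshold defaults to voxelwise $p < 0.001$
(two-sided for t, upper tail for F); clusters use 26-neighbour connectivity
(face, edge and vertex). Familywise error is controlled by permutation of
the maximal cluster size: nuisance effects are fitted once, nuisance
residuals are permuted and the full model refitted (Freedman–Lane), and a
cluster's corrected p is `(1 + #{perm max >= observed}) / (n_perm + 1)`.
This replaces parametric random-field cluster correction deliberately: it is
exact under exchangeability and needs no smoothness estimation.

One discreteness caveat, documented because it shapes the calibration
study in the validation suite: on a desk-scale grid at forming threshold
0.001 a null dataset has ~1–3 supra-threshold voxels, the max-cluster-size
distribution is nearly degenerate, and the achievable test level collapses
well below the nominal 5% (the test stays valid, but conservatively so).
The suite therefore calibrates familywise error at forming threshold 0.01,
where cluster sizes take enough values for the rejection rate to be
informative; the pipeline default remains 0.001.

Missing cognitive scores are handled by listwise exclusion per analysis,
logged via messages; a carrier group with fewer than 4 scored subjects has
its Corsi slope skipped with a warning.

## 5. Preprocessing numerics

* **Band-pass.** "Phase-insensitive" is implemented as zero-phase
  filtering, two ways: an order-4 Butterworth applied forward and backward
  with odd-reflection padding (3x the filter order on each side) to
  suppress edge transients, and a hard FFT frequency mask, which is exactly
  zero-phase and exactly zero outside the band. Both meet the contract
  (in-band sinusoids pass within 5%, one octave outside the band attenuated
  by far more than 20 dB, cross-correlation of input and output peaks at
  lag 0). The Butterworth filter is the default for single series; for 4-D
  runs the FFT path is the default because it filters all voxels in one
  matrix FFT — per-voxel IIR filtering costs minutes per cohort in R for no
  numerical benefit at these series lengths. The per-voxel temporal mean is
  removed.
* **Smoothing.** Separable 3-D Gaussian convolution with
  $\sigma = \mathrm{FWHM}/(2\sqrt{2\ln 2})$ per axis, converted from mm to
  voxels by the grid's voxel size; boundaries use whole-sample reflection,
  so constants are preserved exactly and frame means over the grid to well
  within 1%. The acquisition protocol's "8 mm^3" kernel is read as 8 mm
  isotropic FWHM, the standard usage.
* **Frame discard.** Default 4 frames; 220-frame runs at TR 2.08 s leave
  216 frames. (A 7 min 20 s acquisition at that TR computes to ~212 frames;
  the generator takes the frame count as explicit configuration, default
  220, and does not resolve that inconsistency.)

## 6. The synthetic cohort generator

The generator is the package's test bed: it emulates the study conditions —
3 groups of 22/12/8 subjects, TR 2.08 s, 220 frames, five networks — with
known ground truth, so recovery can be asserted rather than assumed.

* **Geometry.** Default desk-scale grid 16 x 20 x 16 voxels at 3 mm. The
  statistics are grid-size-agnostic; an acquisition-scale 64 x 64 x 32 grid
  is a `voxel_grid()` call away but multiplies runtime roughly by the voxel
  count. Networks are sums of 3 truncated Gaussian blobs (sigma 1.4 voxels,
  i.e. node FWHM ~10 mm), peak-normalized, redrawn until every pair of
  networks has spatial correlation below 0.1 — spatial ICA assumes
  near-disjoint sources, and overlap beyond ~0.2 measurably degrades
  separation at this grid size.
* **Group effects in space.** Per-group, per-network, per-blob amplitude
  multipliers. Defaults: carriers have reduced DMN blob-1 amplitude (HET
  0.75, HOM 0.70); HOM additionally reduced on two ExN blobs (0.70/0.75)
  and two rFP blobs (0.75/0.80) — the qualitative pattern of
  regional intra-network deficits the intra-network stage is meant to find.
* **Coupled time courses.** Band-limited (0.01–0.08 Hz) unit-variance
  series built from shared sources: each coupled pair shares one source,
  injected unshifted into one network and circularly shifted by the pair's
  lag into the other, with weight $\sqrt{|c|}$ on each side; remaining
  variance is idiosyncratic. All pieces are sample-orthogonalized before
  mixing, so a coupling injected at lag 0 is realized exactly in every
  draw, and at other lags up to the (small) correlation between shifted
  orthogonal pieces. The construction requires each network's absolute
  couplings to sum to at most 1.
* **Default couplings.** Controls: DMN negatively coupled to the four
  task-positive networks (−0.15 to −0.30), positive couplings among those
  four (0.10–0.40, strongest SN–rFP at 0.40). HET: the DMN–SN/rFP/lFP
  couplings flip positive — the paradoxical carrier pattern. HOM: SN–rFP
  raised to 0.60, a +0.2 group-specific increase. Magnitude rationale: with
  maximal-|r| selection over 25 lags on 216-sample band-limited series, the
  null selection envelope is ~0.25–0.30 (effective degrees of freedom
  ~2 x bandwidth x duration ≈ 63), so baseline couplings below that
  envelope produce sign-unstable per-subject estimates and could not yield
  sign-consistent group tables; the defaults sit at or just above that
  floor, in the range such studies report.
* **Selection-noise floor.** Even at these couplings, ~3–5% of
  control-group subject pairs select a sign-flipped lag (the Rayleigh tail
  of the lagged cross-correlation envelope exceeds the true coupling).
  These few outliers dominate the within-group variance of z and are the
  binding constraint on between-group detection power at n = 22/12/8; the
  acceptance script measures the resulting detection rate rather than
  assuming it.
* **Noise model.** Voxelwise AR(1) (coefficient 0.3) Gaussian noise of
  marginal SD 1 (network signal peak amplitude is 1), a random per-voxel
  linear drift (SD 0.5 over the run), a constant baseline of 100, and ten
  shared structured nuisance sources: smooth random fields (12 mm) with
  independent per-subject band-limited time courses at amplitude 0.3.
  The structured sources emulate vascular/physiological components and give
  the order-20 decomposition genuine non-network sources to model — with
  only 5 true sources, ICA rotates whitened noise into the source estimates
  noticeably. Their amplitude keeps total structured-noise variance per
  voxel comparable to, not dominant over, the thermal noise. The generator
  deliberately has **no** hemodynamic-response convolution, motion,
  multi-echo or non-stationary physiological modelling; conclusions from
  passing tests transfer to real data only to the extent that registration
  and motion artefacts have been handled upstream.
* **Phenotypes.** Age, education, sex ratios, grey-matter volume, MoCA,
  Corsi span and LEDD are drawn from group-calibrated normals (controls:
  age 47.0 ± 12.2, education 14.7 ± 3.2, 10M/12F; HET: 41.9 ± 14.8,
  12.3 ± 2.1, 5M/7F, Corsi 4.6 ± 0.5; HOM: 51.4 ± 8.1, 11.4 ± 2.3, 6M/2F,
  Corsi 3.9 ± 0.3, LEDD 590.9 ± 358.1). Cognitive battery scores exist only
  for carriers; LEDD only for the treated HOM group. Where the available
  descriptions of such cohorts disagree on sex ratios, the generator
  follows the tabulated counts.
* **Seeding.** Every subject's stream derives from
  `derive_seed(master, subject_id)` — a 31-multiplier string hash combined
  with the master seed by a Lehmer step modulo $2^{31}-1$ — so cohorts are
  bit-reproducible while subjects stay independent; pipeline stages use
  `derive_seed(master, stage)` the same way and can be rerun in isolation.

## 7. Validation suite sizes

The test suite and `scripts/acceptance.R` run at sizes chosen so the whole
suite completes in well under half an hour on one CPU: 1,000 random pairs
for the exhaustive-scan equivalence, 100 subjects per injected lag for lag
recovery, 20 default cohorts for ICA network recovery, 1,000 null datasets
for ANOVA calibration, 200 null datasets (100 permutations each) for
familywise-error calibration, and 50 cohorts for the group-difference
detection rate. The dominant cost is the 20 cohort simulations with group
ICA.

## 8. Known limitations

* Back-reconstructed subject time courses on the desk-scale grid correlate
  ~0.6–0.7 with the injected ones (maps correlate >0.95): with compact
  blobs, few voxels carry each network's temporal signal, and the spatial
  regression implicit in back-reconstruction is noisy. Image-level
  inter-network group analysis is therefore noisier than the
  time-course-level analysis; the generator's time courses are the right
  input for validating the inter-network statistics themselves.
* The naive p of the maximal lagged correlation is anticonservative by
  construction (maximum over 25 lags); the rotation-calibrated p is
  provided but is not part of the primary group pipeline.
* Permutation cluster FWE is exact only under exchangeability; with strong
  group-specific variance differences it is approximate, like all
  Freedman–Lane schemes.
* The LEDD sensitivity check is an uncorrected per-network correlation in
  a group of 8; it can only flag gross medication effects.
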