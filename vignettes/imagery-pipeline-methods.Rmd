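---
title: "Methods: linking auditory imagery to brain structure and representational specificity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking auditory imagery to brain structure and representational specificity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific question

People differ widely in how vividly they experience auditory mental images.
Two kinds of neural correlates of that variation are analysed here: local
gray-matter volume (does brain *structure* predict self-reported vividness?)
and the representational specificity of responses to heard vocal sounds
(do subjects whose cortex distinguishes vocalization types more sharply also
report more vivid imagery?). `imageryvbm` implements the complete analysis
chain for both questions and a synthetic-data generator that emulates the
statistical structure the analyses assume, so every stage can be validated
by parameter recovery against known ground truth.

# Behavioural measures

The auditory imagery instrument has two 14-item subscales rated 1–7
(vividness: clarity of an imagined sound; control: ease of transforming one
image into another). Subscale scores are item means; the total score is the
mean of the two subscale scores, which fixes the item-level weighting
unambiguously. The visual-imagery questionnaire has 16 items rated 1
(perfectly vivid) to 5 (no image); scores are inverted (`6 - mean`) so that
higher always means more vivid in both modalities. Missing or out-of-range
items are rejected with the item index named — no imputation is attempted.
No items are reverse-keyed within the auditory scale.

Association is measured by Pearson product–moment correlation with two-sided
p from the t reference distribution on n − 2 df; partial correlation is the
correlation of least-squares residuals after regressing both variables on an
intercept plus covariates, with df reduced by the number of covariates.
Before averaging, correlations are variance-stabilized with the Fisher
transform `z = atanh(r)`. Because identical map pairs produce r = 1 and an
infinite z, |r| is clipped at `1 - 1e-7` by default (configurable, and
disabled clipping turns |r| = 1 into a domain error); the clip maps r = 1 to
z ≈ 8.4, far outside the realistic range, so finite averages are preserved
without materially moving ordinary values.

# Volume model

All images live on axis-aligned grids with the world coordinate of voxel
(i, j, k)'s *center* at `origin + (index - 1) * voxel_size` (millimetres,
MNI-like axes; no registration is performed — synthetic inputs are already
"normalized"). Structural maps use 1.5-mm isotropic voxels, functional maps
2-mm. ROI spheres contain exactly the voxels whose centers lie within the
radius, boundary inclusive: on a 2-mm grid a 12-mm sphere centered on a
voxel center contains 925 voxels, which is why the default grids have odd
extents (the world origin falls on a voxel center). Smoothing is separable
Gaussian convolution with `sigma = FWHM / (2 sqrt(2 ln 2))` per axis and
zero-padded boundaries (mass of interior impulses is conserved; replicate
padding is available). The analysis mask is the SPM-style *absolute*
criterion: a voxel survives only if every subject's gray-matter value is at
least 0.05 — the conservative reading of the masking rule, chosen because
the alternative (any-subject) produces masks that differ only at tissue
borders where the analysis should not be trusted anyway.

NIfTI-1 I/O supports axis-aligned affines with positive scales only;
anything else raises an explicit unsupported-orientation error rather than
silently reorienting.

# The structure–behaviour GLM

Per voxel, gray matter is regressed on an intercept, one imagery score of
interest, and five nuisance covariates: age, gender (single binary
indicator), total gray-matter volume, forward digit span (a short-term
memory proxy for general cognitive ability), and years of musical training.
Covariates are entered unstandardized — the contrast t is invariant to
affine rescaling of columns given the intercept. The two auditory subscales
are never entered in one design (they are too highly correlated to separate);
the API enforces a single interest column and refuses imagery scores in the
nuisance set. With n = 74 and p = 7 columns the t carries 67 df. Voxels
outside the mask or with (numerically) zero residual variance are excluded
and counted. Reported Z values are the standard-normal deviates with the
same tail probability as the t (or F), computed on the log scale so extreme
statistics do not overflow.

For scatterplots and partial correlations, per-subject mean gray matter over
a detected cluster is residualized on the intercept-plus-nuisance design
(never on the interest score), mirroring how adjusted ROI values are usually
extracted.

# Permutation inference

The reference analysis used random-field cluster correction with a
nonstationarity adjustment; this package substitutes **permutation
inference**, which is valid under exchangeability, needs no smoothness
estimation, and makes the correction's assumptions explicit. The scheme is
Freedman–Lane: residualize the maps on the nuisance-only model, permute
residual rows, add the nuisance fit back, refit the full model, and record
the maximum statistic over the search region. Cluster-level FWE compares
each observed cluster's size (connected components of voxels strictly above
the statistic cutoff for the forming threshold, default P < 0.005, under
18-connectivity — SPM's convention, configurable 6/18/26) against the
permutation distribution of the *maximum* cluster size; small-volume
correction compares the observed peak within a 12-mm a-priori sphere against
the permutation distribution of the sphere-wise maximum. p-values use the
plus-one convention `(b + 1)/(m + 1)`, so the smallest achievable p is
1/(m + 1) and p is never zero. Results are bit-reproducible given (seed,
n_perm); when fewer than n_perm distinct row permutations exist the set is
enumerated exhaustively with a warning. For the condition ANOVA the
exchangeability scheme is condition-label permutation within subject.

Two calibration facts, established by null simulation and worth knowing
when interpreting output: (i) at sparse forming thresholds on small search
volumes the integer cluster-size statistic is heavily tied (typical maximum
sizes 0/1/2), which makes max-size inference *conservative* — attained
type-I error well below the nominal 0.05, never above; the attained level
approaches nominal when the forming threshold is dense enough for sizes to
be well resolved. (ii) the Freedman–Lane permuted t shares a common
per-permutation variance factor across voxels (`x'P(I - Hz)P'x`, an
O(n^-1/2) fluctuation), which slightly fattens the permutation maximum's
tail in very small samples (n ≈ 20) and vanishes by n ≈ 50. The acceptance
suite therefore verifies nominal calibration at n = 50 with a dense forming
threshold and verifies validity (level ≤ nominal) at the sparse study
threshold. Peak-level SVC has no size discreteness and is calibrated as-is.

# Condition ANOVA

The second level consumes per-subject, per-condition t-maps directly
(first-level hemodynamic modelling is out of scope). Per voxel the classical
one-way within-subject decomposition is used: the subject main effect is
absorbed, `F = MS_condition / MS_error` with df (k − 1, (k − 1)(n − 1)) —
(4, 220) for the five intelligible vocalization conditions at n = 56. No
sphericity correction is applied, matching the uncorrected df convention.
Voxels with no between-condition variation at all report F = 0. The
implementation exploits the permutation invariance of the total, subject
and squared sums, so each label permutation costs a single grouped-sum pass;
it is validated against `aov(y ~ cond + Error(subj))` to 1e-10.

# Representational similarity analysis

For each subject the five intelligible-condition t-maps are reduced to
925-vectors over the target sphere (lexicographic voxel order — Pearson r is
order-invariant, the fixed order just makes outputs deterministic), all 10
unordered pairs are correlated, Fisher-transformed and averaged; analogously
the 5 pairs of each vocal condition against the spectrally rotated condition.
The vocal-vs-rotated pairs are also transformed before averaging, for
consistency with the within-vocal procedure. No gray-matter masking is
applied within the sphere. The per-subject summary is then correlated
(optionally partially, with the same five-covariate nuisance set as the VBM
arm) with vividness; the documented sign convention is that negative r means
higher representational specificity in subjects with more vivid imagery.
t-maps, not beta maps, are the substrate: they weight effects by their
error variance, which stabilizes multivariate pattern comparisons.

# Spectral rotation

Rotated control stimuli preserve acoustic complexity while destroying
intelligibility. The chain is: equalize → multiply by `sin(2 pi 4000 t)`
(phase 0 at sample 0, for determinism) → linear-phase FIR low-pass at
3.8 kHz, so a narrowband component at f Hz (200 < f < 3800) lands at
4000 − f Hz and 2 kHz is the fixed point. The equalizer is the exact tap
count of the original design (33) and shapes the signal so the *rotated*
output has approximately the long-term average spectrum (LTAS) of speech:
its target gain at f is `LTAS(4000 - f) / LTAS(f)`. The LTAS itself is
approximated by a documented piecewise log-linear curve — flat below 420 Hz
(the low-frequency roll-off of real speech spectra below 120 Hz is ignored)
and falling 9 dB/octave above — and is shipped as a parameterized function
so the curve can be swapped. Because the target spans ~54 dB, the 33
symmetric taps are fit by least squares with inverse-target (relative)
weighting on a dense frequency grid; below 420 Hz the gain is held constant
(its mirror lies in the flattening top of the rotation band), which keeps
the low end flat within 1 dB between 200 and 400 Hz. The design is accurate
at sampling rates near 16–22 kHz; at 44.1 kHz and above, 33 taps have too
little frequency resolution for tight tracking and the response degrades
gracefully. The low-pass is a Blackman-windowed FIR with its transition
band between 3.8 and 4.2 kHz (≥ 60 dB stopband), sized from the sampling
rate; filters are applied zero-phase with the group delay removed so output
duration equals input duration. Output exceeding [−1, 1] is peak-normalized
with the gain recorded. A pre-modulation low-pass (as in classical analogue
rotation) is available but off by default; only the post-modulation filter
is part of the canonical chain.

The vocalization synthesizer exists to provide deterministic fixtures:
harmonic stacks with category-specific fundamental contours (neutral ~130
Hz, screams 750–900 Hz, …), roll-off, breath-noise mix and, for pulsed
categories like laughter, slow amplitude modulation, under an attack/decay
envelope. When no duration is given it is drawn from a normal distribution
with mean 1018 ms and SD 326 ms truncated at 300 ms, matching the stimulus
set's descriptives. It makes no claim to perceptual realism.

# The synthetic-data generator

The generator's defaults are the study conditions: 74 structural subjects
(ages 20–81, mean 42.6, SD 17.1), of whom the first 56 form the functional
arm; latent correlations 0.68 (vividness–control), 0.57 (vividness–visual
vividness), 0.40 (control–visual, chosen once to keep the target matrix
positive definite — the value is not reported anywhere and only mildly
affects joint draws); scale scores are truncated latent Gaussians with the
reported means and SDs (vividness 4.96 ± 0.95 on [1,7], control 5.28 ± 0.95,
inverted visual vividness 3.63 ± 0.81 on [1,5]). Truncation attenuates
realized correlations by roughly 0.01–0.02, well inside a single cohort's
sampling interval. Covariates: binary gender (P = 40/74), digit span
rounded-normal 7.08 ± 1.21 clamped to 4–9, musical training present in
30/74 with 6.0 ± 4.5 years, total gray matter 700 ± 60 arbitrary units,
all independent of the imagery scores.

Gray-matter maps are a radial baseline ("brain" falling below the 0.05 mask
threshold at the box edge) plus a smooth between-subject noise field
(white noise smoothed at 6-mm FWHM, rescaled to SD 0.02) plus, inside an
ellipsoidal effect region (semi-axes 10 × 9 × 9 mm at the grid center), a
subject offset `d_i = 0.05 (0.46 z_viv + sqrt(1 - 0.46^2) eps_i)` — so the
ROI-mean gray matter correlates with vividness at 0.46 in the population by
construction. The smooth noise field adds a small extra variance component
to the ROI mean, attenuating the realized correlation by a few hundredths;
the 50-replicate recovery tests sit comfortably inside the 95% sampling
interval. Values are floored at zero; maps are returned unsmoothed and the
analysis stage applies its own 10-mm smoothing, as a real morphometry
pipeline would.

Condition t-maps implant both effects of interest inside the target sphere.
For subject i with per-subject similarity target
`z_i = 0.83 + 0.10 (−0.34 z_viv + sqrt(1 − 0.34²) eps)` and
`r_i = tanh(z_i)`, condition j's sphere pattern is
`sqrt(r_i) g_i + sqrt(1 − r_i)(λ P_j + sqrt(1 − λ²) q_ij)` with `g_i` a
subject-shared pattern, `P_j` a condition pattern common to all subjects
(λ = 0.5 — this common part is what the repeated-measures ANOVA detects)
and `q_ij` idiosyncratic. The expected pairwise within-sphere correlation is
then r_i (pattern length 925 keeps the sampling noise of each pair around
0.01), the cohort mean Fisher-z similarity is ≈ 0.83 with SD 0.10, and the
population similarity–vividness coupling equals −0.34 exactly. The rotated
condition shares `g_i` with a mixing weight solved from
`corr(vocal, rotated) = sqrt(r_i rr_i)` so that its expected similarity to
each vocal condition is `tanh(z_rot_i)`, with
`z_rot_i = 0.55 + 0.12 (−0.42 z_viv + …)`; the −0.42 coupling is the
reported value, while the mean 0.55/SD 0.12 are the package's own choice
(no cohort descriptives are printed for this summary; rotated stimuli are
represented more distinctly than intelligible ones, hence a mean well below
0.83). Outside the sphere all conditions share a subject background plus
noise, so the ANOVA is null there. Maps are labelled kind-"t" and scaled to
a t-like range; every downstream statistic is scale-invariant.

Ground truth (effect masks, implanted offsets, similarity targets) is
returned in a separate `truth` element that no analysis function accepts —
the firewall that makes parameter-recovery tests meaningful.

## What the generator does and does not emulate

It reproduces the *statistical couplings* the analyses estimate, realistic
score distributions, and the geometry conventions (grids, spheres, masks).
It does not attempt anatomical realism (no cortical folding, no tissue
classes), spatially structured artefacts, inter-subject misregistration, or
first-level hemodynamics. Passing recovery tests therefore demonstrates
that the estimators are correct and calibrated under their assumptions —
not that those assumptions hold in any particular empirical dataset.

## Problem sizes

Default grids are compact bounding boxes — 33 × 39 × 33 at 1.5 mm
(structural) and 31 × 37 × 31 at 2 mm (functional), odd extents so the
origin is a voxel center — rather than whole-head volumes: they hold the
12-mm ROI sphere and the implanted effect with wide margins while keeping
50-replicate recovery studies and 200-replicate null calibrations pleasant
to run interactively. All dimensions are configurable; the statistical
parameters (n, couplings, noise levels) do not change with the grid.

# Pipeline and reproducibility

`run_pipeline()` executes `simulate → vbm → anova → rsa → report` in
dependency order from a YAML or list config (CLI flags override config
keys), writing cluster tables as CSV with JSON sidecars (seed and
permutation count recorded), correlation reports as JSON, and a run
manifest with an MD5 checksum of every output. All randomness flows through
explicit seeds; identical (config, seed) runs produce identical reports.
Missing upstream outputs name the stage to run first.

# Known limitations

* Permutation inference replaces random-field nonstationary cluster
  correction; corrected p-values are not expected to match an RFT
  implementation numerically.
* Cluster-size FWE is conservative at sparse forming thresholds on small
  volumes (tie discreteness); consider the SVC peak test for small a-priori
  regions.
* The equalization filter's 33-tap budget limits spectral tracking at high
  sampling rates.
* Only axis-aligned, positively oriented NIfTI affines are supported.
* The sphere-count convention (inclusive boundary at voxel centers) is
  validated against the printed 925 count at 2 mm; at other voxel sizes it
  simply follows the same rule.
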