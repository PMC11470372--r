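---
title: "Methods: emotion-concept geometry and searchlight RSA in emorsa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: emotion-concept geometry and searchlight RSA in emorsa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emorsa)
```

# The scientific question

Conceptual knowledge of emotion categories — how strongly feature words
like "yelling" or "sweating" relate to anger, sadness, and so on — varies
substantially across people. `emorsa` implements a pipeline for testing
whether that variation is reflected in the geometry of brain responses
to emotional faces and voices: each participant's own conceptual
dissimilarity structure is used as the model in a searchlight
representational similarity analysis (RSA) of their single-trial fMRI
response patterns, with nonparametric group inference.

Because the pipeline is meant to be verifiable without access to
scanner data, a synthetic-data module generates behavioral and imaging
inputs with *known planted structure*, and the test suite checks that
every stage recovers what was planted.

# Conceptual dissimilarity

A rating matrix holds one participant's integer ratings (1–7) of 40
feature words against each of 7 emotion categories. The conceptual
dissimilarity between emotions is the Pearson correlation distance of
their rating rows, `d = 1 - r`, so `d = 0` means identical rating
profiles up to a positive affine map and `d = 2` perfect
anti-correlation. `rdmFromRatings()` is therefore invariant to adding a
constant to a row or rescaling it positively; a constant row is an
error naming the offending emotion rather than a silent `r = 0`
substitution, which would bias group averages toward `d = 1`.
Distances below 1e-12 are snapped to exactly 0 so that definitional
zeros survive floating-point round-off.

## Nonmetric MDS

`nonmetricMds()` minimizes Kruskal stress-1 by Guttman-transform
majorization. The starting configuration is the classical (Torgerson)
metric solution from `cmdscale`. Each iteration fits disparities by
isotonic regression of the configuration distances taken in
dissimilarity order, then applies the Guttman update. Ties in the
dissimilarities are handled by the primary approach: tied entries are
ordered by their current configuration distance, so no order constraint
binds within a tie block. Iteration stops when the stress improvement
falls below `tol = 1e-6` (or at `maxIter = 300`); convergence-iteration
counts are data-dependent and reported in the result rather than
assumed. On distances that embed exactly in the plane the classical
start is already optimal and the stress is numerically zero; on
monotonically distorted distances the isotonic step undoes the
distortion and stress again approaches zero — both behaviours are
asserted in the test suite.

## Ward clustering

`wardClustering()` uses the Murtagh–Legendre "Ward2" convention:
the Lance–Williams recurrence on *squared* dissimilarities with merge
heights reported on the square-rooted scale, i.e. `hclust(method =
"ward.D2")`. The convention matters because the alternative ("Ward1",
squaring omitted) produces different heights from the same input; the
chosen convention is recorded on the returned object as a
`"convention"` attribute. The test suite re-derives the full merge
sequence with an independent Lance–Williams implementation and requires
agreement to 1e-10.

# Categorization confusions

`confusionToDissimilarity()` subtracts each off-diagonal confusion
count from the largest off-diagonal count. Note the direction this
implies: frequently confused pairs receive *small* values and behave as
similar, which is exactly why a *positive* correlation with conceptual
dissimilarity is the expected sign of the conceptual-knowledge effect.
The transform is applied exactly as stated; its occasionally repeated
verbal gloss ("larger means more confused") is the opposite of what the
formula does, and the documentation flags rather than "fixes" this.
The matrix is left asymmetric — row/column roles differ — and only the
upper triangle feeds the correlation. `correlateUpperTriangles()`
z-scores both triangles first (a no-op for Pearson r, kept for scale
comparability of the reported values) and returns r with the t-based
two-sided p on `n_pairs - 2 = 19` degrees of freedom for 7 emotions.

# Single-trial estimation (LSS)

`fitLss()` fits, per trial, an OLS GLM with the target trial as one
boxcar–HRF regressor and all remaining trials collapsed into a second
regressor, plus optional nuisance columns, a discrete-cosine high-pass
basis with 128-s cutoff (`floor(2·T·TR/128)` orthonormal columns) and
an intercept. The HRF is the canonical double-gamma (peak delay 6 s,
undershoot delay 16 s, dispersions 1 s, undershoot ratio 1/6, 32-s
support, peak-normalized); convolution runs on a microtime grid of
`TR/16` and the volume is sampled at a slice-time reference of 0.5 TR.
No AR(1) prewhitening is applied: plain OLS keeps the estimator exactly
linear, which the recovery tests exploit.

Two structural facts are worth stating plainly. First, adding any
linear combination of the included DCT columns to the data provably
leaves trial betas unchanged (the perturbation lies in the design's
column span), and the tests assert this at 1e-8. Second, LSS is a
deliberately misspecified model: when trial amplitudes differ, the
collapsed "other trials" regressor cannot represent the data exactly,
and correlations with the intercept/DCT columns leak a small bias into
the target estimate even for temporally separated trials. The exact
equivalences — recovery of planted amplitudes to 1e-6 and equality with
the joint all-trials GLM to 1e-8 — hold when the target regressor is
orthogonal to every other design column, which the tests realize by
separating trials beyond the 32-s HRF support and fitting without
intercept and filtering (`highpassCutoff = NULL, intercept = FALSE`);
with two trials the LSS design *is* the joint design and equality holds
for arbitrary data. The boxcar length follows the event table's
duration column by default, with `boxcarDuration` available to model a
full 12-s trial epoch (four 3-s stimuli) as a single block, which is
the default reading for the scanner task design.

# Low-level control features

`autocorrPitch()` estimates f0 per frame as the lag of the peak of the
mean-removed, r0-normalized autocorrelation inside
`[sr/fmax, sr/fmin]`, refined by parabolic interpolation; frames whose
peak falls below 0.3 are unvoiced. Frame (2048 samples) and hop (512)
defaults are declared choices at common speech sample rates, not
derived quantities. Because a single scalar f0 per stimulus would make
a per-emotion Pearson distance undefined, `pitchFeatureTable()`
resamples each stimulus's voiced f0 track to a fixed length;
`featureRdm()` then averages feature vectors within emotion (one vector
per emotion — the reading that matches correlating features "across
each emotion pair") before computing `1 - r`, with the
stimulus-pair-averaged alternative available via `average = FALSE`.
Image-based control features (e.g. deep or HMAX-style C2 descriptors)
enter as a precomputed feature table; their extraction is out of scope.

# Searchlight RSA

Sphere membership uses Euclidean distance in world coordinates under
the affine, honoring anisotropic voxels (e.g. 3.3 × 3.3 × 3 mm); on a
3-mm isotropic grid a 4-mm sphere holds the center plus its 6 face
neighbors (diagonals sit at ~4.24 mm). Centers with fewer than
`minVoxels = 3` members are dropped and recorded — Pearson patterns
over one or two voxels are degenerate. Within each sphere, trial betas
are averaged per emotion, the neural RDM is `1 - cor` of the seven
pattern vectors, and the strict lower triangles (column-major, a frozen
but arbitrary order) of neural and model RDMs enter an OLS regression.

Response and predictors are z-scored and an intercept included, so the
single-model coefficient *is* the Pearson correlation of the triangles
and the Fisher transform `atanh` is well defined; without
standardization coefficients could exceed 1 and `atanh` diverge, which
is why standardize-then-OLS is the default (both choices are exposed).
Exact fits are clipped to `1 - 1e-7` before `atanh`. With several
models, coefficients are standardized partial effects; collinear model
sets are an error rather than a silent pseudo-inverse.

# Group inference

`groupTmap()` computes the one-sample t against zero per voxel
(zero-variance voxels get `t = 0` by convention). `tfce()` enhances the
positive part by integrating `extent^E · h^H · dh` over thresholds with
the field-standard `E = 0.5, H = 2`, 26-connectivity, and
`dh = max/100`; an isolated voxel of height h therefore maps to
approximately `h^3/3`, a closed form the tests verify, and the
implementation (an incremental union-find over descending thresholds,
in C++) is exact for the discretized sum, not an approximation.

`signPermutationTest()` builds the null by flipping each subject's map
sign with a fair coin — the exchangeability argument needs only
symmetry of the per-subject error distribution about zero — and
recording the maximum TFCE value per permutation; all `2^n` sign
patterns are enumerated when that is no larger than `nPerm`. Corrected
p values use the add-one convention `(1 + #{max >= obs})/(nPerm + 1)`,
so the smallest attainable p is `1/(nPerm + 1)` and p is monotone in
the observed statistic; z scores are the one-sided normal transform
capped at the permutation resolution, thresholded at 1.65 (corrected
p < 0.05, one-tailed) for the significance mask. Each map (observed and
permuted alike) uses its own `max/nSteps` as the TFCE step: the
statistic is then equivariant under rescaling and no fixed absolute
step has to be guessed for null maps. The max-statistic correction is
the permutation analogue of family-wise error control; parametric
random-field cluster correction is deliberately not implemented.

For activation-style analyses, `voxelwiseEmotionF()` provides a
voxelwise one-way repeated-measures F (condition fixed, subject
blocking; df `(6, 6(n-1))` for 7 conditions), and `conjunctionMin()`
the minimum-statistic conjunction: the elementwise minimum plus the
voxels significant in *both* maps under their per-map thresholds (the
conjunction-null criterion, not the weaker global-null variant).

# The synthetic world

`plantedWorld()` fixes: a group prototype RDM (by default a
circumplex-style configuration of unit vectors whose cosines give a
valid correlation structure, with near pairs such as fear/anger and
sad/disgust); subject idiosyncrasy as symmetric Gaussian jitter of the
prototype (SD 0.1 by default) projected back to a valid correlation
distance by eigenvalue clipping and renormalization; observation noise;
and an imaging grid (default 10×10×10 at 3 mm) with a 3×3×3-voxel
signal region. Task-design generators enumerate the rating task (7
blocks × 40 words = 280 trials) and the scanner session (4 blocks × 7
emotion trials × 4 actor stimuli + 2 catch trials = 114 records, with
4.5-s pre-fixation, 3-s stimuli, 3-s post-fixation, 12-s block rests;
catch trials are appended after the last trial of randomly chosen
blocks, flagged, and ignored by analysis).

Ratings and beta patterns use an exact-correlation construction: a
row-centered, whitened Gaussian basis multiplied by a factor of the
implied correlation matrix, so at zero noise the empirical RDM of the
generated data equals the planted RDM *exactly*, not just in
expectation. Exactness needs at least `n_emotions + 1` dimensions (40
words; regions of ≥ 8 voxels); smaller regions fall back to an
in-expectation construction. Ratings are affine-mapped to mean 4,
SD 1.2 on the 7-point scale, rounded half-up and clipped — tolerance
0.05 in the recovery tests absorbs the rounding; `discretize = FALSE`
exposes the continuous path for exactness checks. Confusions follow a
softmax in negative dissimilarity with temperature 0.3 and `d(i,i)=0`,
making the planted conceptual–confusion link monotone by construction.

`calibrateBetaNoise()` bisects the trial-noise SD until the recovered
emotion-pattern RDM correlates at a target level (default 0.5) with the
planted subject RDM. The evaluation unit defaults to a single 4-mm
searchlight sphere inside the region — the unit at which the downstream
statistic lives — with the whole region available as an alternative;
the distinction matters because a 27-voxel region supports noticeably
higher recovery than a 7-voxel sphere at the same noise.

What the generator does *not* emulate: spatial autocorrelation of fMRI
noise, scanner drift beyond an optional cosine term, motion artifacts,
hemodynamic variability across regions, and realistic stimulus content.
Passing tests therefore demonstrate the estimators' correctness and
calibration under idealized noise, not robustness to every property of
real scanner data.

# Problem sizes and reproducibility

The test suite runs planted-recovery at 20 subjects on a 10×10×10 grid
with 1,000 permutations, and estimates the family-wise error rate from
200 null datasets at 500 permutations; the acceptance script uses 500
null datasets at 1,000 permutations. These sizes keep a full run in the
minutes range on one CPU while leaving Monte-Carlo error well inside
the asserted bounds (the FWER bound allows two Monte-Carlo standard
errors above 0.05). All generators are bit-reproducible given a seed:
randomness is drawn under a saved-and-restored RNG state, and
subject-level seeds are derived deterministically from the world seed.

# Known limitations

- The searchlight loop is plain R over centers; it is comfortable at
  simulation scale (~1,000 centers in seconds) but would want blockwise
  vectorization for whole-brain masks at full resolution.
- TFCE enhances positive values only, matching one-sided inference on
  positive associations; two-sided use requires running both signs.
- LSS inherits the usual single-trial caveats at short inter-trial
  intervals (see the bias discussion above); the package reports what
  OLS yields rather than attempting regularized variants.
- The repeated-measures F assumes sphericity; no correction is applied,
  as it serves only to define activation masks for conjunction in the
  simplified univariate path.
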