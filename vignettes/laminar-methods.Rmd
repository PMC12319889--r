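---
title: "Depth-resolved analysis of hippocampal BOLD responses: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Depth-resolved analysis of hippocampal BOLD responses: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(hippolaminar)
```

## The problem

Gradient-echo BOLD fMRI at 7 T can resolve signal as a function of depth
within the folded gray-matter sheet of the human hippocampus. Two obstacles
stand between a depth profile and a neuroscientific claim. First, GRE-BOLD
is weighted toward large draining veins, and the hippocampal venous tree is
organized so that the bias differs between subfields: sulcal veins run along
the inner (stratum radiatum) surface of the subiculum and CA1, subependymal
veins along the outer (stratum oriens) surface of CA2–CA3. An apparent
laminar "peak" may therefore be vascular, not neural. Second, at 0.8–0.9 mm
voxels the hippocampus is a low-SNR, physiologically noisy target, and the
depth dimension spans only two to three voxels.

`hippolaminar` implements the full analysis chain for this setting —
geometry, vascular mapping, multi-echo relaxometry, noise characterization,
task GLM and group inference — together with a synthetic-data generator with
known ground truth, so every stage is testable without access to raw MRI
data.

## Depth sampling on subfield surfaces

All geometry lives on a `subfield_surface_set`: inner, midthickness and
outer triangulated surfaces with one-to-one vertex correspondence and one
subfield label per vertex (subiculum, CA1–CA4, DG). "Outer" is the stratum
oriens side, "inner" the stratum radiatum side; depth fraction 0 is the
outer boundary, 1 the inner boundary, and values above 1 denote extension
bins beyond the inner boundary toward the hippocampal sulcus.

`build_sampling_scheme()` splits the piecewise-linear path outer →
midthickness → inner of every vertex into 20 coordinates equidistant in arc
length, with bins placed at the segment endpoints (bin 0 is the outer
boundary value, bin 19 the inner boundary value; sampling at segment
centers was the alternative and is not used). The midthickness surface
obeys the equivolume principle and is the only landmark that survives
folding, so the bin nearest to it in arc length is *replaced* by the
midthickness point, bit-exactly; ties are broken toward the outer side.
Replacement rather than respacing preserves the equidistant grid for all
other bins. For CA1 and CA2 the sampling continues 10 further bins beyond
the inner boundary along the local mid → inner direction at the last bin
spacing, reaching into stratum lacunosum-moleculare. CA4 and the DG have no
well-defined inner/outer pair; they form a two-bin scheme in which all DG
vertices constitute the "inner" bin and all CA4 vertices the "outer" bin,
each sampled at its midthickness point (the least partial-volumed single
locus).

Volumes are resampled at scheme coordinates by piecewise tricubic Lagrange
interpolation on the voxel grid (exact for polynomials up to degree 3),
with stencils clamped at volume edges; coordinates outside the volume
yield missing values and flag their vertex rather than being silently
zeroed. A fixed scheme is converted once into a sparse interpolation
operator so 4D series are sampled with one sparse-matrix product per run.

## Vascular mapping and the venous bias

Veins are detected on susceptibility-weighted images with a multiscale
Hessian vesselness filter (eigenvalue ratios with alpha = beta = 0.5,
structure-norm constant c set to half the maximal Hessian Frobenius norm
per scale, response restricted to dark tubes, maximum over scales 0.3–1.2
mm). Arteries are detected on time-of-flight images with a slice-wise
multi-level 2D Haar wavelet detail-energy score smoothed in-plane with a
1-voxel Gaussian; this filter is a reconstruction of an under-specified
custom filter and is documented as such. Filter outputs are min–max
rescaled over a brain mask to [0, 100], veins negated into [-100, 0] (the
anchoring percentiles were an open choice; min–max over the mask is the
declared one), and projected onto the inner and outer surfaces by tricubic
sampling at the vertex coordinate.

Vessel density per subfield and surface is the fraction of vertices passing
a strict threshold, −3 a.u. for veins and 1 a.u. for arteries; the same −3
a.u. rule defines the vein exclusion mask used when aggregating laminar
profiles. The quantity that links anatomy to function is the
inner-minus-outer density difference Δρ per subfield.

The breath-hold experiment turns this anatomy into a functional bias
estimate: hypercapnia drives a global flow increase, so the signal change
(active minus rest, computed per depth and echo after high-pass filtering
with a 246 s cutoff period and removal of the first and last volume of each
run) is vascular in origin. Echoes are combined with inverse-TE weights
`w_i = TE_i^-1 / sum TE_j^-1`, which penalize long echoes where
off-resonance artifacts dominate. An ordinary least-squares line through
the signal-change profile over the 20 core bins (extension bins belong to
different laminae and are excluded) gives the per-subject, per-subfield
bias slope, and the mixed model `slope ~ delta_rho + (1|subject) +
(1|subfield)` quantifies how much of the laminar bias the vascular
asymmetry explains.

## Multi-echo T2* and noise characterization

Baseline T2* per depth is fitted to rest-condition echo means by
Levenberg–Marquardt nonlinear least squares on `S(TE) = S0 exp(-TE/T2*)`,
initialized from the log-linear fit, which also serves as the fallback for
non-convergent depths (flagged, never silently dropped). The default echo
times are 2, 6, 10, 14, 17, 21 ms (an alternative listing replaces the last
echo with 20 ms; the generator takes the TE vector as a parameter, and the
discrepancy is recorded rather than resolved).

Temporal SNR and the depth-resolved Weisskoff test both use only the
volumes of the mental-arithmetic control condition, selected by a
deterministic rule: a volume belongs to a condition if its acquisition
midpoint, shifted back by 2 volumes (≈4.4 s of hemodynamic delay; the
shift is configurable since no canonical value exists), falls inside a
trial window. The Weisskoff test draws, for every depth and every subset
size N, 50 random vertex subsets without replacement (a fixed-seed choice;
the draw count is not prescribed anywhere), averages their time courses and
records the temporal SD: pure thermal noise decays as `sigma/sqrt(N)`
(log–log slope −0.5), while the plateau at large N is the structured
physiological noise floor. Hemispheres are pooled at the vertex level
before subsetting.

Nuisance regressors follow the anatomical-component approach: ROI 1 is the
high tail of the first-pass GLM residual map (values above 3 SD of the map;
the map must be centred — the rule is a tail rule, and feeding it an
all-positive residual-SD image degenerates to selecting everything), ROI 2
is an anatomical noise region (white matter in vivo, the non-sheet
background in the phantom). Voxel time courses are linearly detrended and
standardized; ROI 1 keeps the smallest set of leading principal components
explaining at least 50 % of the ROI variance (variance measured as squared
singular values of the standardized matrix), ROI 2 keeps exactly 5. All
components are orthogonalized against the intercept, the linear detrending
term and the six motion regressors — including the detrending term makes a
pure motion span vanish exactly — and renormalized.

## Task GLM and laminar contrasts

The task design contains three regressors of interest: the autobiographical
memory trial split at the button press into a construction phase (cue to
press) and an elaboration phase (press to trial end), plus the
mental-arithmetic condition. Boxcars are convolved with the canonical
double-gamma HRF (peak delay 6 s, undershoot delay 16 s, unit dispersions,
peak:undershoot ratio 6, 32 s support) and sampled at volume midpoints.
The first three volumes of a run are discarded; a discrete-cosine basis
with periods above 128 s enters as regressors (equivalent to pre-filtering
both sides of the model); motion and nuisance sets are appended
unconvolved; rank deficiency is an error that names the collinear columns.

Depth time courses are baseline z-transformed — standardized by the mean
and SD over the math-condition volumes — *before* model fitting, so
contrast values are expressed in units of baseline variability. The model
is then fitted by robust weighted least squares: iterated per-volume
inverse-variance weighting with the volume variances pooled over depths (or
voxels). Two numerical guards matter: variances are floored at 1e-4 of
their median, because the unregularized iteration can assign a volume
unbounded weight, interpolate it exactly and diverge; and on homoscedastic
data the weights equalize only as the pooled dimension grows (the deviation
from OLS scales like the weight noise, `sqrt(2/n_units)`), which is why the
first pass runs at the voxel level.

The two contrasts are `memory > math` (mean of the AM phases minus math)
and `pre > post` (construction minus elaboration), per depth.

## Inference layer

Paired subfield comparisons use the exact Wilcoxon signed-rank test: W is
the sum of positive-difference ranks and the two-sided p-value is
`2 * min(P(W <= w), P(W >= w))` capped at 1, computed from the exact null
distribution (zero differences are dropped with a warning; ties are
refused). Families are adjusted with Hochberg's step-up procedure; the
density family has five members (subiculum, CA1, CA2, CA3, CA4/DG) and the
slope family four (the two-bin CA4/DG scheme has no slope) — the only
family sizes consistent with the full set of printed adjusted values the
tests reproduce. Per-subject inner/outer densities are averaged over
hemispheres before ranking.

Depth-model comparisons fit three random-intercept models per subfield —
`z ~ (1|subject)`, `z ~ depth + (1|subject)` and
`z ~ depth + depth^2 + (1|subject)`, with depth rescaled to [0, 1] (the
fraction, not the bin index, for scale invariance) — by REML, and compare
baseline vs linear and linear vs quadratic with Kenward–Roger approximated
F-tests, Benjamini–Hochberg corrected. Contrast-versus-contrast and
masked-versus-unmasked comparisons use
`z ~ depth + factor + depth:factor + (1|subject)` with sum-to-zero factor
coding, so dropping a term yields marginal (Type III) F-tests. Marginal and
conditional R² use the variance-decomposition definition (fixed /
fixed + random + residual; conditional adds the random share). On balanced
layouts the Kenward–Roger denominator df reproduce the classical
closed forms (`n_subjects - n_groups` for a between-subject factor,
`N - n_subjects - 1` for a within-subject covariate), which the tests
assert to 1e-6; under the null at 8 subjects × 20 depths the F-test's
rejection rate at the 5 % level is verified to lie in [0.03, 0.07] over
1000 simulate-and-refit replicates, with the p-values uniform against that
parametric reference (KS < 0.05).

## The synthetic scene

The generator emulates the statistical and geometric structure the analysis
assumes, not the MR physics of acquisition. A spiral cross-section
(hippocampal crescent) is extruded longitudinally; the inner surface is
offset from the outer along local cross-section normals, and the
midthickness is placed at the local *equivolume* depth: for local curvature
radius r the equal-volume annulus radius is `sqrt((r_in^2 + r_out^2)/2)`,
which lies closer to the convex boundary than the arithmetic midpoint
(outer rings hold more area) and collapses to the midpoint on a flat slab.
Subfield labels are assigned by transverse arc-length fractions in
anatomical order.

Default scene conditions, chosen once as a realistic 7 T regime and then
left alone:

* sheet thickness 2.5 mm, outer spiral radius 10 mm — at the 0.9 mm task
  voxels this leaves just under three voxels across the sheet; thinner
  sheets cannot carry a recoverable laminar shape at this resolution;
* baseline signal 1000 a.u., thermal noise SD 30 a.u. (voxel tSNR ≈ 33,
  thermal-dominated at the voxel level as in real high-resolution EPI);
* low-rank structured physiological noise: sinusoids at ≈0.3 Hz
  (respiratory) and 0.11 Hz (aliased cardiac) with smooth random spatial
  loadings of amplitude 8 and 6 a.u., plus a first-order polynomial drift;
* task responses of ~0.5–1.5 % signal change with subfield-specific laminar
  shapes: linear inner-increasing ramps in the subiculum and CA2, a
  quadratic CA1 profile peaking at depth fraction 0.75, a quadratic
  mid-depth CA3 profile, flat CA4/DG responses, and a weak flat response to
  the control condition;
* T2* between 24 and 36 ms, depth-linear per subfield, shortest in the
  subiculum (high myelin content);
* vein centerlines hugging the inner surface of the subiculum and CA1 and
  the outer surface of CA3, arteries near the outer subicular surface —
  the planted Δρ asymmetry;
* breath-hold runs of 6 (rest, transition, active) blocks plus a final rest
  volume at TRvol 40.992 s; during active volumes T2* lengthens by
  `1 + 0.15 exp(-d / 1 mm)` near vein centerlines (kernel truncated at
  4 mm), the single-parameter venous-bias ground truth; transition volumes
  carry half the effect;
* task runs of 44 trials of 17.6 s (AM and math randomly interleaved,
  inter-trial fixation 2.2 or 4.4 s chosen uniformly), 489 volumes at TRvol
  2.21 s; button-press latencies are lognormal with median 4 s, truncated
  to [1 s, trial length − 2 s].

Everything stochastic is reproducible from a seed, and generators restore
the caller's RNG state.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: EPI distortion and k-space artifacts, motion-corrupted
volumes (the motion table is a slow random walk used only as regressors),
receiver bias fields, depth- or region-dependent HRF shape, physiological
noise that is not low-rank, and the convolutional drainage of veins across
depths (the bias kernel is local).

## Problem sizes and numerical choices

The test-suite and acceptance computations run at deliberately scaled desk
sizes, stated here as the package's own choices: phantoms of 8 × 24 to
10 × 36 vertex grids, 8 simulated subjects for the task experiment, 1000
replicates for T2* recovery and the mixed-model calibration (2000 in the
acceptance script), 1000 vertices × 400 volumes for the Weisskoff suite.
Tie-breaks and degeneracies are resolved explicitly: the midthickness
replacement ties toward the outer side; zero-thickness vertices collapse
their bins, warn and are flagged; constant vesselness input rescales to
zeros with a warning; numerically flat regions produce zero vesselness (a
structure-norm floor relative to the data range); exact-fit GLMs floor
their variance estimates and warn; empty high-residual ROIs fall back to
the anatomical ROI with a warning.

## Known limitations

The rWLS estimator equals OLS only in the large-pooling limit; at a few
hundred pooled units its coefficients can differ from OLS by a noticeable
fraction of a standard error. The Kenward–Roger wrapper is exercised only
for random-intercept models, which is all this analysis needs. The Haar
artery filter is a documented reconstruction, not a reimplementation of a
published algorithm. The CA2 density test's raw p-value is unreported in
the literature this package models; the family adjustment is insensitive to
it over a wide range, and the worked examples fix it conservatively at 1.
GIFTI I/O is a minimal ASCII codec sufficient for the package's own
surfaces; binary-encoded files from other tools are not read.
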