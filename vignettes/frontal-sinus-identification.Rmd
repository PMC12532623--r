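---
title: "Frontal-sinus silhouette matching: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frontal-sinus silhouette matching: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sinusid)
```

## The problem

The frontal sinus is a paired air cavity in the frontal bone whose outline is
so individually variable that even monozygotic twins differ. When primary
identifiers (DNA, fingerprints, dental records) are unavailable, a
postmortem CT of unidentified remains can be compared against an antemortem
clinical CT: if an axial silhouette of the sinus from the two scans is
essentially the same shape, the remains are very likely the person in the
clinical record.

`sinusid` implements this comparison as a quantitative pipeline. Each CT
slice is reduced to a 200 x 100 binary silhouette (sinus black on white,
the cavity being the air below the 200 HU bone threshold). Two binary
keypoint pipelines — an ORB-style extractor and an AKAZE-style extractor,
both written from first principles in this package — turn each silhouette
into a set of keypoints with fixed-length bit-string descriptors. A pair of
images is scored by brute-force matching: every antemortem descriptor is
paired with its Hamming-nearest postmortem descriptor, and the
**similarity score is the mean matched Hamming distance** (in bits). The
score is 0 when the images are identical; lower means more similar.
Identification is then a threshold decision on the score, and its quality is
summarized by Welch's t-test between matched (same individual) and
mismatched (different individuals) pairs, by ROC analysis (AUC, Youden
cutoff, TPR, FPR), and by observer-reliability metrics (rTEM and the
coefficient of reliability R) for repeated measurements.

Because the CT data behind this kind of study cannot be redistributed, the
package carries a synthetic silhouette generator that reproduces the
statistical structure the analysis needs, and every claim the test suite
makes is made on synthetic cohorts (or on analytic fixtures with exact
oracles).

## The synthetic cohort model

`generate_shape()` renders a sinus as a union of 1–4 overlapping lobes.
Each lobe is a closed radial polygon $r(\varphi) = r_0\,(1 + a \sin(k\varphi
+ \phi_0))$ with per-case random base radius, vertical squash, scallop
frequency $k \in \{4,\dots,9\}$, phase and amplitude; lobes left of the
midline are shrunk by the `asymmetry` ratio. This produces the arcaded,
scalloped outlines seen in real sinus silhouettes, with high
between-individual shape variance coming from the random lobe geometry. A
configurable fraction of cases (`simple_shape_frac`) is instead rendered as
a near-rectangle — the shape class known to cause false positives, because a
rectangle offers few distinctive keypoints.

`perturb_shape()` models the difference between the antemortem and
postmortem renderings of the *same* sinus: a rotation of at most a few
degrees (head pose), a sub-pixel translation, and a morphological
erosion/dilation of small radius that mimics selecting a slightly different
axial slice. Defaults (`perturb_rot_deg = 3`, `perturb_shift_px = 2`,
`perturb_morph_px = 1`, `simple_shape_frac = 0`) are deliberately small
because in the emulated workflow an examiner picks the postmortem slice most
similar to the antemortem image.

Covariates follow the emulated study design exactly: 135/180 male, 125/180
scan intervals under 30 days, 81/180 ages under 60 years, assigned as exact
counts and shuffled by the cohort seed. Ages are drawn uniformly within
each age stratum and intervals uniformly (short stratum) or exponentially
with a 1920-day cap (long stratum); only the stratum memberships matter to
the subgroup analyses.

Determinism is a contract: one root seed produces per-case child seeds via a
fixed affine counter scheme, so cohorts are reproducible byte-for-byte and
extensible without reshuffling existing cases.

What the generator does *not* model: 3-D anatomy, partial-volume HU
textures, scanner differences, pathology, or the true population
distribution of sinus complexity. A passing separation test on synthetic
cohorts therefore shows that the pipeline's machinery discriminates shapes
under the stated perturbation model — it does not by itself establish
real-case error rates.

## Preprocessing

`threshold_hu()` binarizes a Hounsfield raster at 200 HU (below 200 HU
black, 200 HU and above white) — the convention that makes the air-filled
sinus a black region surrounded by white bone. `extract_sinus_silhouette()`
automates the manual cut-out step with an explicit rule: inside a
user-supplied ROI, the sinus is the **largest 4-connected black component
that does not touch the ROI border** (an enclosed cavity must be surrounded
by bone). `normalize_canvas()` crops to the foreground bounding box plus a
fixed 4-pixel margin, rescales preserving aspect ratio so the foreground
fits the margin-reserved 192 x 92 interior, centres it on the white
200 x 100 canvas and re-binarizes at 0.5; scaling into the reserved
interior makes a second normalization pass the identity up to resampling.
ROIs are 0-based and half-open with the origin at the top-left, stated once
and used everywhere. How a real sinus should be delimited from adjacent
air cells is genuinely under-specified in practice; the enclosed-component
rule is this package's convention, not anatomy.

HU rasters are read from headerless CSV or 16-bit grayscale PNG storing
`HU + 1024`. The PNG writer bundled here (`write_hu_png16()`) emits a
minimal standards-compliant uncompressed 16-bit PNG, since no installed R
package writes 16-bit PNGs; `png::readPNG()` reads the files back exactly.

## The ORB-style extractor

Binary silhouettes are two-level images, which makes gradients and circle
arcs degenerate, so detection runs on a Gaussian-smoothed copy
(`detect_sigma = 1`) and description on a sigma-2 copy. The stages:

* **FAST-9**: a pixel is a corner iff at least 9 contiguous pixels on the
  16-pixel Bresenham circle of radius 3 are all brighter than $I(p)+t$ or
  all darker than $I(p)-t$ (`fast_threshold = 0.08` on [0,1] images). The
  corner score is the sum of $|I(c)-I(p)|$ over circle pixels of the
  detected polarity; non-maximum suppression keeps strict 3 x 3 maxima, so
  plateaus yield nothing.
* **Harris ranking**: $\det M - 0.04\,\mathrm{tr}^2 M$ of the 7 x 7
  block-summed Scharr structure tensor ranks corners; the strongest 500
  keypoints across a 4-level, factor-1.2 bilinear pyramid are kept.
* **Orientation**: the intensity-centroid angle $\theta = \mathrm{atan2}(m_{01},
  m_{10})$ over a radius-15 disc, with $\theta = 0$ by convention when both
  moments vanish. Coordinates are x rightward, y downward.
* **Steered BRIEF**: 256 point-pair tests drawn once from an isotropic
  Gaussian (sd = patch/5, coordinates clamped so rotated samples stay inside
  the 31 x 31 patch) from a fixed seed; bit $i$ is
  $I(p + R_\theta a_i) < I(p + R_\theta b_i)$. The pattern is seeded
  Gaussian rather than the original learned pattern: bit-exact parity with
  any third-party build is a non-goal, robustness under rotation is tested
  directly instead.

## The AKAZE-style extractor

This is an "AKAZE-lite": the published core, minimally.

* **Nonlinear scale space**: 4 octaves x 4 sublevels with
  $\sigma_i = 1.6 \cdot 2^{o + s/4}$ and evolution time $t_i =
  \sigma_i^2/2$ in each octave's own pixel units. The image evolves by
  explicit steps $L \leftarrow L + \tau\,\mathrm{div}(g\,\nabla L)$ in
  conservative form with zero-flux boundaries, where $g = 1/(1 +
  |\nabla L|^2/k^2)$ (Perona–Malik g2) and $k$ is the 70th percentile of
  the nonzero gradient histogram (300 bins), recomputed per octave.
* **Fast Explicit Diffusion**: a cycle of $n$ steps $\tau_j = \tau_{\max} /
  (2\cos^2(\pi(2j+1)/(4n+2)))$ advances time by $\tau_{\max} n(n+1)/3$;
  the smallest sufficient $n$ is chosen and the steps rescaled so their sum
  hits the target increment exactly ($\tau_{\max} = 0.25$).
* **Detection**: scale-normalized Hessian determinant
  $(\sigma^2 L_{xx})(\sigma^2 L_{yy}) - (\sigma^2 L_{xy})^2$ from repeated
  3 x 3 Scharr filtering, thresholded at $10^{-4}$; a keypoint must beat
  its 8 in-layer and 9+9 adjacent-layer neighbours strictly (ties yield
  nothing). The $\sigma^4$ scaling is the standard normalization that makes
  an analytic Gaussian blob of width $\sigma_b$ peak at layer
  $\sigma \approx \sigma_b$, and the test suite verifies exactly that on a
  single-octave ladder. Across octaves the comparison is imperfect: pyramid
  downsampling attenuates discrete derivatives of coarse layers, biasing
  octave competition toward finer scales. This is a known discretization
  property, accepted here; silhouette keypoints live at fine scales anyway.
* **Orientation**: dominant gradient direction from Gaussian-weighted
  Scharr gradients within radius $6\sigma$, scanned with a sliding
  60-degree sector.
* **M-LDB descriptor**: over a $\theta$-rotated square patch of half-width
  $10\sigma$ sampled on a 24 x 24 lattice, the 2 x 2, 3 x 3 and 4 x 4 grid
  partitions each compare every unordered cell pair on three channels (mean
  intensity, mean $L_x$, mean $L_y$, derivatives rotated into the keypoint
  frame): $(6 + 36 + 120) \times 3 = 486$ bits, stored padded to 61 bytes.

Keypoints are sorted canonically (response descending, then y, then x)
before matching, so results are independent of storage order.

## Matching and the similarity score

`brute_force_match()` pairs every query descriptor with its Hamming-nearest
target descriptor; ties go to the lowest target index. There is no ratio
test and no cross-checking — the score is defined over *all* matches, and
filtering would change the statistic. The matching direction is fixed
antemortem → postmortem (a symmetric average is available but off by
default). `similarity_score()` returns the mean matched distance; zero
keypoints in either image raise an `insufficient features` condition that
cohort code records as missing, never as a score of 0.

## Evaluation statistics

`score_matrix()` computes all $n^2$ AM x PM scores (features extracted once
per image). The diagonal is the matched group; within any case subset the
off-diagonal entries whose row *and* column belong to the subset form the
mismatched group, so subgroup comparisons are fully within-subgroup.
Subgroups follow the study design: sex, scan interval split at 30 days, age
split at 60 years.

Welch's t-test (via `stats::t.test`, Satterthwaite degrees of freedom,
two-sided) compares the groups; reports carry each group's n, range, mean
and SD in the descriptive-table layout. ROC analysis treats **lower scores
as positive** (identified iff score ≤ threshold, ties at the cutoff count
positive); the AUC uses the Mann–Whitney pair-count form, which equals the
trapezoid of the threshold-sweep curve identically, and the reported cutoff
maximizes Youden's J with ties resolved to the smaller threshold. The
Youden rule is this package's choice — score-table publications rarely
state their cutoff criterion — and is therefore a flagged convention, as is
the pooled-2n-sample variance in $R = 1 - \mathrm{TEM}^2/s^2$ (a
per-subject-mean variant is available via an argument).

`tables_from_scores()` runs the same statistics directly from a long-format
per-pair score table plus covariates, bypassing images entirely: that is
the path that would reproduce a published score listing, and the test suite
exercises it with synthetic score tables of known structure. The published
supplementary listings themselves are not redistributable text and are not
bundled.

## Reliability

TEM $= \sqrt{\sum d_i^2 / 2n}$ over two sessions, rTEM as a percentage of
the grand mean (bounds 1.5% intra-, 2.0% inter-observer), and $R$ against
0.75. The acceptance script emulates re-collection by re-perturbing each
postmortem slice with a 1-degree/1-pixel jitter and re-scoring; with the
default extractors the ORB score is quite stable under this jitter while
the AKAZE score, built on fewer keypoints per silhouette (typically 5–30
here), is noticeably noisier — a genuine property of mean-Hamming scores
over small keypoint sets, reported as measured.

## Numerical choices and degenerate inputs

* Gaussian smoothing uses a truncated (3 sigma), renormalized sampled kernel
  with mirror padding — the method-of-images extension that matches the
  diffusion stage's zero-flux boundaries; the linear-limit test (g ≡ 1 vs
  Gaussian) agrees within 0.02 of the intensity range.
* Bilinear resizing is centre-aligned with clamped borders; silhouette
  re-binarization thresholds at 0.5.
* All-zero gradient images fall back to contrast factor k = 0.03 with a
  warning; constant images yield zero keypoints; both extractors raise a
  typed condition when no keypoint survives, and cohort code records those
  pairs as missing (a cohort with more than 10% missing entries errors).
* Extremum and NMS ties are strict everywhere: plateaus yield no keypoint.
* Random draws all flow from explicit seeds; `withr::with_seed` keeps the
  global RNG state untouched.

## Problem sizes used by the checks

The packaged checks run cohorts of n = 60 (separation, 5 seeds, both
methods), n = 30 (perturbation-degradation trend over morphological radii
{0, 1, 3, 6}, 5 seeds), n = 180 for score-table statistics, 20 subjects for
reliability emulation and n = 200 for variance-component recovery; these
sizes give stable statistics for the properties asserted while keeping the
default run brief.

## Worked example

```{r example, eval = FALSE}
library(sinusid)

co <- generate_cohort(20, synth_params(seed = 3))
sm <- score_matrix(co, "akaze")
sp <- split_matched_mismatched(sm)
welch_t(sp$matched, sp$mismatched)
roc_analysis(sp$matched, sp$mismatched)
```

## Known limitations

* Bit-exact parity with any third-party ORB/AKAZE build is a non-goal; the
  published algorithm cores are implemented, with the deviations documented
  above (seeded BRIEF pattern, g2-only conductivity, no sub-pixel
  refinement, full M-LDB without channel subsampling).
* Cross-octave detector responses are biased toward fine octaves (see
  above).
* The synthetic generator supports method validation, not case-level
  error-rate claims for real CT material.
* Only two-session reliability is implemented; generalized multi-observer
  TEM is out of scope.
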