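---
title: "Robust Gaussian fitting for serial crystallography: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robust Gaussian fitting for serial crystallography: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sxrobust)
```

## The problem

Serial crystallography (SX) detectors record hundreds of millions of
diffraction frames. Almost every per-pixel decision in their analysis —
"is this pixel part of a Bragg peak?", "is this detector pixel broken?" —
reduces to the same statistical question: the bulk of the data follows a
single Gaussian-noise structure (the background, or the population of
healthy pixels), contaminated by outliers that are exactly the objects of
interest. Plain means and standard deviations are biased by those outliers;
`sxrobust` provides the robust primitives that are not, and the two SX
applications built on them: a Bragg-peak finder and a bad-pixel mask maker.

The package models data with the simplest geometric families: a constant
$a$ for 1D data, a line $a + bx$ for 2D, a plane $ax + by + c$ for image
patches. The output of every fitter is the model parameters, the inlier
noise scale $\sigma$, and per-point inlier flags.

## Scale estimation: MSSE

Given squared fitting errors $r_j^2$ sorted ascending, the estimator walks
the sorted sequence. With $p$ model parameters already fitted, the running
scale at index $k$ is

$$\sigma_k^2 = \frac{\sum_{j \le k} r_{(j)}^2}{k - p},$$

and point $k + 1$ is accepted while $r_{(k+1)}^2 \le \lambda^2 \sigma_k^2$.
The first violation stops the scan; everything ordered after it is an
outlier. The cutoff $\lambda$ (default 3, sensible range 2–4) is justified
by the Gaussian mass inside $\pm\lambda\sigma$: more than 95% within two
scales and more than 99.99% within four. The scan starts at `k_min`
(default 12), the smallest population on which a scale is considered
estimable.

Numerical choices:

* Sorting is stable; ties are broken by original index so results are
  reproducible to the bit.
* `minimum_residual` (default 0) floors $|r|$ before squaring. On
  quantized integer images many residuals can be exactly zero, which would
  otherwise lock the scale at 0; the floor encodes the quantization step.
* All residuals exactly zero with a zero floor is a valid degenerate case:
  $\sigma = 0$, everything an inlier.
* The weighted variant excludes zero-weight points outright and uses the
  weight-scale-invariant form
  $\sigma_k^2 = (\sum_{j \le k} w_j r_{(j)}^2 / \sum_{j \le k} w_j)\cdot
  k/(k-p)$, so binary weights reproduce the unweighted estimator on the
  kept subset exactly and rescaling all weights changes nothing.

One caveat discovered during development and worth knowing about: when the
scan starts at a tiny `k_min` on a large window (thousands of points), the
dozen residuals nearest the fitted model are occasionally, by chance,
tight enough that index 13 already violates the test, and the scale locks
onto that micro-cluster. Inside the fitters this cannot be the right
answer — the `certain_ratio` fraction of the data is by definition highly
likely to be inliers — so the fitters start the scan at
$\max(k_\mathrm{min}, \lceil \mathrm{certain\_ratio}\cdot N\rceil)$.
Direct calls to `msse()` keep the plain `k_min` default.

## Robust optimization: FLkOS

The fitters minimize the $k$-th order statistic of the squared residuals,
where $k = \lceil \mathrm{likely\_ratio} \cdot N \rceil$ is a rough, safe
underestimate of the structure size. The default `likely_ratio = 0.5`
encodes, for image work, "at least half of any reasonable window is
background". Each iteration:

1. fits the model by ordinary least squares to the current subset;
2. computes squared residuals for **all** points and stable-sorts them;
3. takes as the next subset the block of ranks
   $[k - s + 1,\, k]$, with $s = \max(p + 1, \lceil
   \mathrm{certain\_ratio}\cdot N\rceil)$ capped at $k$.

The block ends at rank $k$ so that it stays inside the presumed inlier
set while still touching its boundary, which is what drags the model
toward the structure. Iteration stops after `opt_iters` (default 12)
rounds or as soon as the subset repeats; the subset whose fit achieved the
lowest $k$-th sorted residual is retained.

Two refinements follow the iteration:

* **Inlier polish.** The best-subset fit is handed to MSSE, and the
  parameters are then refit by least squares on the segmented inliers and
  re-segmented once. Fitting only the rank block (roughly 30% of the data,
  conditioned on residual magnitude) leaves the estimator with about twice
  the variance of the inlier-only oracle; the polish removes that gap
  while the MSSE segmentation keeps outliers out of the refit.
* **Threshold flags.** Reported inlier flags are exactly
  $\{|r| \le \lambda\sigma\}$ (with the residual floor applied), so flags,
  scale and threshold are always mutually consistent.

Initialization uses `model_value_init` when given (the first subset is
then the rank block under that model — fully deterministic), otherwise a
seeded uniform random subset. The optimizer converges to the same optimum
from almost any start, so the initialization mainly affects iteration
count. All randomness flows through `rng_seed` under a fixed named RNG,
and every internal windowed fit uses the same seed, which makes window
processing position-independent: fitting a sub-image gives bit-identical
results to fitting the same window inside the full array.

`fit2skewed` decays `certain_ratio` linearly to a floor of 0.05 across the
iterations. With a skewed noise density (a Gaussian convolved with an
exponential component, as photon-counting backgrounds often are) the
shrinking block slides toward the mode instead of straddling the skewed
tail. The linear schedule is the simplest monotone choice; the floor keeps
the block above $p + 1$ points.

`downsampled_size` fits a seeded uniform subsample (values $\ge N$ are a
no-op, so downsampling can be enabled unconditionally), after which flags
are computed for all points against the fitted model.
`median_of_fits` repeats the fit with consecutive derived seeds (default 3
repeats — enough to reject a single unlucky draw without tripling every
call) and takes elementwise medians of parameters and scale.

On the ambiguity in the published description of the likely ratio (one
passage reads 0.5%, another 0.5): 0.5 is adopted. A likely ratio of 0.5%
of a typical analysis window would fall below `k_min` and make the rank
block degenerate.

## SNR

The separability statistic is

$$\mathrm{SNR} = \frac{x_p - \mu_B}{\sigma_B},$$

signed, so deficient (dead) pixels are strongly negative. One published
rendering of this statistic divides by the background mean instead of the
scale; that form is inconsistent with thresholding at a multiple of the
noise scale (the universal SX practice, threshold 6 by default) and is not
used here. `snr()` refuses a non-positive scale; callers that can
encounter degenerate windows apply a floor first.

## Background maps

`fit_background()` tiles the image with `win_y` × `win_x` windows
(default: one window, the whole image). Each window is fitted robustly —
a tilted plane (`num_model_params = 4`: three plane parameters plus the
scale) or a robust constant (`num_model_params = 1`) — and every covered
pixel receives the *model prediction at that pixel* (so tilt survives into
the map) and the window's scale. With `num_strides = n`, the tiling is
repeated at offsets $\mathrm{round}(i \cdot \mathrm{win}/n)$ per axis and
per-pixel values are averaged across the shifted tilings, which smooths
window-boundary seams. Edge windows are clipped; a clipped window is
fitted whenever it retains `k_min` + 1 usable pixels, otherwise its pixels
inherit the nearest fitted pixel's model. Masked pixels never enter any
fit and carry `NA` in the output maps.

On the 256 × 256 ramp-plus-noise fixture the normalized residual image
$(I - \hat\mu)/\hat\sigma$ is standard Gaussian to within a few percent,
which is the property the peak finder relies on.

## Peak finding

Three steps per frame:

1. **Candidates** — valid pixels that are strict maxima of their 3 × 3
   neighbourhood and exceed the median of their local window (default
   32 × 32). Candidates are processed in decreasing intensity and capped
   at `max_peaks` (default 1024, a customary per-frame cap in SX peak
   lists).
2. **Local model** — a robust plane over the candidate's window; the
   candidate's SNR is its intensity minus the plane prediction at the
   seed, over the window scale. This replaces the crude median threshold
   with an accurate local one. Windows are clipped at panel edges, never
   padded; a window too masked to fit discards its candidate with a
   recorded reason. A candidate with SNR exactly at the threshold
   (default 6) is accepted — the `>=` convention keeps re-runs on
   quantized data idempotent.
3. **Growth** — 4-connected flood fill from the seed over unclaimed valid
   pixels above the plane prediction, confined to the seed's window.
   Grown pixels are claimed, so peak membership is a partition and a
   connected spot yields exactly one peak. Reported statistics:
   background-subtracted total intensity, intensity-weighted centroid,
   pixel count, seed SNR.

A frame is a **hit** when it has strictly more peaks than
`min_peaks_for_hit`. Frames are independent; `parallel_map()` provides the
order-preserving map over frames whose results are identical to the
serial run for any worker count.

## Bad-pixel masks

Calibration stacks (dark fields, or near-flat bright fields) should make
every healthy pixel behave alike. `compute_feature_maps()` computes plain
per-pixel temporal statistics — deliberately non-robust, so a defective
pixel biases *its own* feature. `abnormality_map()` then models normal
behaviour robustly in 64 × 64 windows (a windowed robust constant) and
returns each pixel's signed SNR against its window model. `make_mask()`
thresholds $|\mathrm{SNR}|$ at 6 — two-sided, because dead pixels sit far
*below* the model — and sets one bit per feature in an 8-bit code
(0 = good). A derived "dead" bit marks pixels whose temporal mean *and*
temporal standard deviation are both at least the threshold below the
model: constant, silent pixels. At most 8 classes fit the code budget.

The feature registry ships temporal mean, standard deviation, median and
range; production calibration pipelines use a longer, detector-specific
feature list, and the registry is the extension point for those.

## What the generators emulate — and what they do not

The synthetic generators are first-class, seeded, and carry ground truth:

* `gen_1d_dataset` — Gaussian inliers plus uniform outliers (the classic
  demo: inliers at 0, outliers on [1.5, 6.5]; or 70% of 100 points inlier).
  Labels follow the generator: an outlier drawn inside the inlier band
  keeps its label, which bounds attainable recovery accuracy and is the
  irreducible label noise of all recovery tests.
* `gen_line_dataset`, `gen_plane_dataset` — planted line/plane, Gaussian
  noise, box or boosted-pixel outliers.
* `gen_diffraction_pattern` — tilted-plane background, i.i.d. Gaussian
  noise, 2D Gaussian spots with recorded centres and nominal SNR
  (amplitude over noise scale). The default gradient is gentle so that
  spot apices always rank inside the candidate cap.
* `gen_frame_stack` — i.i.d. Gaussian frames at a flat base level with
  planted hot (+10 scales mean offset), dead (constant 0) and flickering
  (3× standard deviation) pixels.

Real SX frames have structure these fixtures do not: Poisson statistics
and detector gain stages, water/ice rings with radial curvature, panel
gaps and geometry, beam-centre artefacts, per-pulse intensity jitter.
Passing the package's tests demonstrates the statistical machinery on its
stated model — Gaussian single-structure plus outliers — not performance
on any particular facility's data. The local-window design is exactly what
transfers: within a 32-pixel window, a smoothly curved background is well
approximated by a tilted plane.

## Problem sizes and runtime choices

The shipped tests and the acceptance script use 256 × 256 frames for the
peak finder (20 seeds), one 1024 × 1024 flat-noise frame for the
false-alarm rate, 512 × 512 × 100 stacks for the mask maker (20 seeds),
and 1000-point vectors for the 1D studies (50 seeds). These sizes make the
full study a few minutes of desk compute while keeping every estimator in
its intended regime (thousands of points per window). The FLkOS iteration
is implemented in C++ (subset least squares plus a stable sort of all
residuals) because windowed fitting calls it thousands of times per frame;
every aggregate step around it is vectorized R.

## Known limitations

* One inlier structure per call: no sequential fit-and-remove, no
  multi-structure segmentation, no scale estimators beyond the sorted
  squared-residual scan.
* Models stop at planes; radially symmetric backgrounds are out of scope
  (the windowed plane is the intended workaround).
* The candidate's detection threshold is refined exactly once (median
  first pass, then the robust plane); no further iteration.
* I/O covers TIFF and delimited text plus JSON sidecars; container
  formats used at facilities (HDF5 families) are not read or written, and
  coordinates are 1-based (row, col) as everywhere in R.
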