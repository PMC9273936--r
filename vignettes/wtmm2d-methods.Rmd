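---
title: "Multifractal analysis of rough surfaces with the 2D WTMM method and the saturation rescue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multifractal analysis of rough surfaces with the 2D WTMM method and the saturation rescue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Many biological and medical images — mammograms are the motivating
case — are rough surfaces: the gray level fluctuates at all scales,
and the fluctuation statistics (monofractal vs multifractal, the
Hurst/Hölder exponents) carry diagnostic information.  The
wavelet transform modulus maxima (WTMM) method estimates these
statistics by following the maxima of a continuous wavelet transform
across scales.  Sensor saturation clips a fraction of pixels to a
common maximal value, creating exactly flat plateaus.  Flat regions are
infinitely smooth, so a clipped surface is no longer everywhere
singular; in practice the skeleton of maxima lines acquires a
population of spurious lines associated with the saturated regions, and
the negative-moment statistics collapse.  `wtmm2d` implements the full
analysis chain and the *rescue* procedure — a two-stage pruning of the
skeleton — that removes those spurious lines and restores valid
statistics on images with up to roughly 20 % saturated pixels.

## The analysis chain

**Transform.**  For a surface $f$, the transform at position
$\mathbf b$ and scale $a$ is the pair
$T_{1,2}(\mathbf b, a) = a^{-2}\int \psi_{1,2}\!\big((\mathbf x-\mathbf
b)/a\big)\, f(\mathbf x)\,d^2x$ with $\psi_1 = \partial G/\partial x$,
$\psi_2 = \partial G/\partial y$ and $G = e^{-|\mathbf x|^2/2}$,
summarized by the modulus $M = \sqrt{T_1^2 + T_2^2}$ and the argument
$A = \arg(T_1 + iT_2)$.  `cwt()` evaluates this by periodic
frequency-domain convolution with analytically dilated kernels, so no
spatial sampling bias enters at small scales.  The sign convention
makes $(T_1, T_2)$ point *uphill* (along the gradient of the smoothed
surface).  Imported non-periodic images are mirror-extended to twice
their size and cropped after the transform.

**Maxima.**  At each scale the WTMM are the points whose modulus is a
local maximum along the argument direction (`detect_wtmm()`, bilinear
interpolation of the two probes one pixel away).  They lie on connected
maxima chains (`chain_wtmm()`); the modulus maxima along the chains
(WTMMM, `detect_wtmmm()`) are the points linked across scales.  The
production path (`wtmm2d::wt_skeleton()`) obtains the per-scale WTMMM by a
resolution-matched rule: a WTMM point is retained when its modulus is
maximal among the WTMM within a Chebyshev radius of $\max(1, a/2)$
pixels.  At the smallest scales this reduces to the 8-neighbour
local-maximum rule; at larger scales the radius grows with the wavelet,
matching the modulus correlation length along the chains.  Without this,
pixel-scale chain fragmentation inflates the maxima population at large
scales and the line density no longer falls off as $a^{-2}$ — the
behaviour required of a two-dimensional support (the measured
$\tau(0)$ is then far from $-2$).

**Skeleton.**  Maxima lines are seeded at the smallest scale only — a
line must point to a singularity as $a \to 0^+$ — and linked upward
greedily in ascending distance order with a search radius equal to the
target scale; unmatched lines terminate, and unclaimed WTMMM at upper
scales never seed new lines (`link_scales()`).  The set of lines is the
space-scale skeleton; dropping the positional information gives the
sheaf of $(\log_2 a, \log_2 M)$ curves whose slopes estimate Hölder
exponents.

**Partition functions and spectra.**  With $\mathcal L(a)$ the lines
alive at scale $a$ and $\sup_{a' \le a} M$ each line's running supremum,

$$Z(q,a) = \sum_{l \in \mathcal L(a)} \Big(\sup_{a'\le a} M_l\Big)^q
  \sim a^{\tau(q)},$$

and the canonical (Boltzmann-weighted) averages $h(q,a)$ and $D(q,a)$
give $h(q)$ and $D(q)$ as slopes against $\ln a$
(`partition_functions()`, `fit_spectra()`).  All sums are evaluated in
log space so arbitrary $q$ cannot overflow.  For a monofractal surface
$\tau(q) = qH - 2$.  The direct Legendre transform
$D(h) = \min_q(qh - \tau(q))$ is provided only as a numerical
cross-check (`legendre_check()`); the canonical route is the primary
estimator because the direct transform is fragile.

**Ensembles.**  Calibration runs average the partition functions over
replicate surfaces before fitting (`ensemble_average()`); the default
is the arithmetic mean of $Z$, of the $h(q,a)$ numerators and of the
$D(q,a)$ numerators per $(q,a)$ cell.  A pooled variant (weights
normalized by the pooled partition sum, i.e. all surfaces treated as
one canonical ensemble) is available via `pooled = TRUE`; on
desk-scale ensembles the plain mean behaves better at negative $q$
because it averages independent step-like extreme-line contributions
instead of following the single ensemble-wide extreme line.

**Fit window and quality rule.**  Spectrum fits use the fixed window
17–56 px at every condition.  The usable moment range is the maximal
contiguous run of $q$ containing $q = 1$ on which both the $h(q,a)$
and $D(q,a)$ fits reach $R^2 \ge 0.99$; the reference work judged
power-law quality visually, and the fixed threshold makes the criterion
testable.  The razor is sharp: ensembles of few small surfaces sit
close to the threshold at $q \lesssim -1$, and the binary usable-range
boundary can move by half a grid step between otherwise equivalent
runs.

## The synthetic calibration surfaces

`fbm_surface()` synthesizes fractional Brownian motion by Fourier
filtering: complex Gaussian white noise shaped by $|k|^{-(H+1)}$, DC
zeroed, real part of the inverse transform, linear rescale to
$[0, 255]$.  The full calibration design is 32 replicate surfaces of
$1024 \times 1024$ pixels for each $H \in \{0.1, 0.3, 0.5, 0.7\}$.
Saturation is injected by `apply_saturation()`: the critical value is
the empirical $(1-p)$-quantile of the heights and everything above is
clipped to it, so the plateau is exactly flat and ties only raise the
achieved fraction.

What the simulator reproduces: the power spectrum ($\propto
|k|^{-2(H+1)}$, verified by the periodogram tests), the
structure-function slope $2H$ at moderate lags, and the monofractal
skeleton statistics.  What it does not: the synthesis is periodic, so
the largest analysis scales are starved of infrared (sub-box) energy.
In the fixed 17–56 px window this produces a known *underestimation*
of $H$ that worsens as the window approaches the box size — at
$512^2$ the fitted $\tau$-slope for $H = 0.7$ drops to about $0.52$,
at $1024^2$ it is about $0.63$.  Hurst-recovery checks therefore run
at $1024^2$, the size of the original calibration, where the residual
deficit matches the underestimation the calibration itself reports.
Passing tests on these surfaces say nothing about non-Gaussian or
genuinely multifractal data.

### The analysis noise floor

A subtle but essential modelling choice: with exact arithmetic, the
wavelet response deep inside a clipped plateau decays to nothing
(smooth Gaussian tails of the surrounding terrain), and *no maxima at
all* appear there — the saturation artifact this package exists to
remove would be invisible.  Real pipelines compute at finite precision,
and their response inside flat regions is a small white noise whose
*maxima count* (one per correlation area $\sim a^2$) is independent of
the noise amplitude.  `wt_skeleton()` therefore adds a seeded white
noise of relative amplitude $2^{-23}$ (single-precision epsilon) to the
analyzed copy of the surface.  Everywhere rough this is invisible
(≪ 10⁻⁴ of any genuine modulus); inside plateaus it seeds the weak
spurious maxima lines — the population with extremely low modulus and
overall negative slope that grows with the saturation level.  Because
the count is amplitude-invariant, the floor is a mechanism switch, not
a tunable parameter; `noise_floor = 0` recovers the ideal transform.

## The rescue procedure

`prune_skeleton()` applies two ordered, inclusive filters:

1. **Modulus filter (MF):** remove every line whose modulus at its
   first (smallest) skeleton scale is $\le$ MF.  Calibrated registry
   (surfaces in $[0,255]$): MF $= 16, 48, 96, 192$ for
   $H = 0.7, 0.5, 0.3, 0.1$ (`mf_for_hurst()`; geometric interpolation
   between calibrated values, with a warning).
2. **Slope filter (SF):** among survivors, remove every line with
   adjusted slope $m_{\mathrm{adj}} = (\log_2 M_{\mathrm{first}} -
   \log_2 M_{\mathrm{last}})/\log_2 M_{\mathrm{last}} \ge 0.5$.

A line meeting both criteria counts under MF only, so the removal
percentages are additive.  Two degenerate cases the formula leaves
open: single-scale lines have no trend and face the modulus filter
only; survivors whose terminal modulus is $\le 1$ (so the $\log_2$
denominator degenerates) are removed when their modulus decays from
first to last scale — exactly the weak negative-sloping artifact
class — and kept otherwise.  "First scale" is read as each line's first
skeleton scale (every line starts at the smallest scale, and the
filter's purpose is to catch lines born weak there); reading it as the
scale-index-1 convention of the sheaf axis (14 px) is available via
`mf_scale` and measurably degrades both filters.

**Absolute units.**  The modulus scale of a WTMM implementation depends
on its wavelet normalization and the image amplitude convention, and
the calibrated MF values are only meaningful in the reference units.
The package aligns units at run time by quantile matching
(`recalibrate_mf()`): the skeleton moduli of an *unsaturated* reference
ensemble are rescaled (`rescale_skeleton()`; exactly equivalent to
rescaling the surface heights, by linearity) so that the registry
threshold sits at the 1 % lower quantile of first-scale moduli —
i.e. the modulus filter removes about 1 % of clean lines, matching the
reference behaviour where clean removal is small.  Spectrum slopes are
invariant under this alignment.  The pipeline applies it by default
(`mf = "recalibrate"`); `auto_filter_params()` additionally offers an
experimental outlier-based threshold choice, off by default.

## Numerical choices

* **Scale grid:** $a_0 = 7$ px, 8 voices per octave, capped at $N/6$;
  this covers the conventional example scales (20, 56, 158 px) and
  puts 14 grid scales in the fit window for $N \ge 512$.
* **Spectral decimation:** the transform at scale $a$ is band-limited
  by $e^{-a^2|k|^2/2}$, so for $a \ge 8$ the field is evaluated
  exactly on a grid decimated by $s \le a/4$ (powers of two); maxima
  positions are then quantized to $s$ px, far below the linking radius
  $a$.  This is what makes $1024^2$ ensembles tractable; skeletons
  with and without decimation were compared and differ only in the
  fragile single-line negative-moment tail.
* **Modulus floor:** grid points below $10^{-12}$ of the field maximum
  are not WTMM candidates (double-precision dirt, far below the
  analysis noise floor).
* **Ties:** cross-scale matching breaks distance ties by line id;
  plateau runs of equal moduli along a chain contribute their first
  point in traversal order.
* **Degenerate inputs:** constant surfaces transform to exactly zero
  (no maxima); saturation of a constant surface is rejected; spectrum
  fits require at least 4 scales with surviving lines in the window.

## Problem sizes used by the tests and the acceptance script

The shipped tests validate the machinery on closed-form fixtures
(exact power-law skeletons, cusp surfaces $|\mathbf x - \mathbf
x_0|^h$ with a mild angular modulation to lift the rotational
degeneracy of the maxima ring) and on fBm ensembles of 4 replicates at
$1024^2$ per condition; the acceptance script uses 32 replicates at
$1024^2$ for the unsaturated and 20 %-saturated ensembles (the full
calibration design) and 8 replicates for the intermediate levels.

## Known limitations

* The $h(q)$ curves of desk-scale monofractal ensembles are not flat
  to better than ~0.15–0.3 across $q \in [-3, 5]$: the extremes of
  the sup-modulus distribution at each scale are order statistics of a
  shrinking line population, which tilts $h(q)$ upward at negative $q$
  and downward at positive $q$.  Slopes and intercepts of $\tau(q)$
  are much more robust than the flatness of $h(q)$.
* The density of spurious maxima lines inside saturated regions is
  detector-specific.  Under this package's detection rules the
  artifact population is smaller than the reference calibration
  reports (at 20 % saturation the modulus filter removes ~15 % of
  lines versus the reported 21.8 %), and after the rescue the usable
  moment range extends to about $q = -1$ rather than $-2$ on
  32-surface ensembles.  The direction and ordering of every effect
  reproduces; the absolute artifact counts do not fully.
* Surfaces with $H$ outside $(0, 1)$, genuinely multifractal
  synthesis, and the two-threshold slope-filter variant are out of
  scope.
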