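---
title: "Quantifying curvature sorting and clathrin assembly on membrane tubes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying curvature sorting and clathrin assembly on membrane tubes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tubequant)
```

## The experimental system

Supported membrane tubes (SMrT templates) are narrow (~47 nm) bilayer tubes
formed by flow-extrusion of surface-tethered vesicles inside a flow cell.
Hypertonic shock introduces ~408 nm spherical buds along the tubes, so a
single continuous membrane displays both high curvature (tubes) and low
curvature (buds) — "beads on a string". Fluorescence time-lapse imaging of a
lipid dye, a labeled curvature-sensing protein (epsin), and labeled clathrin
on these templates yields three quantitative readouts, each implemented as a
pipeline in this package:

1. **Curvature sorting** — how strongly a protein partitions to the highly
   curved tube relative to the bud (`analyze_ratio_field()`).
2. **Clathrin assembly kinetics** — per-event time constants of clathrin
   focus growth from kymographs (`analyze_kinetics_movie()`).
3. **Foci density** — clathrin foci per 100 um of tube after a fixed
   incubation (`analyze_foci_movie()`).

Supporting arithmetic covers one-site binding titrations (`fit_one_site()`)
and coating-layer correction of scanning-EM diameters
(`correct_diameter()`). Because raw movies for this kind of experiment are
rarely deposited, the package includes a forward simulator
(`simulate_budded_template()`, `simulate_assembly_movie()`,
`simulate_binding_titration()`) whose ground truth makes every stage
testable end to end.

## Surface-area photometry and the enrichment ratio

Both tubes (d ~ 47 nm) and buds (d ~ 408 nm) are at or below the optical
resolution, so the net fluorescence of each object is proportional to its
membrane surface area: a tube contributes $\pi d_{tube}$ per unit length and
a bud $\pi d_{bud}^2$ in total. The protein surface density of an object is
therefore proportional to its protein:lipid fluorescence ratio. Normalizing
each ratio by the mean bud ratio of the same field yields the enrichment

$$\mathrm{ratio}_{tube} =
  \frac{(F_{prot}/F_{lip})_{tube}}{\langle F_{prot}/F_{lip}\rangle_{bud}},$$

which is 1 for a curvature-insensitive protein and ~13 for PIP2-recruited
epsin. Normalization is per field (not pooled across fields) so that
illumination and labeling differences cancel; the summary operation accepts
a grouping key for multi-field experiments. Tube-versus-bud comparisons use
Welch's unequal-variance t-test — the variance of the two classes differs by
an order of magnitude, so the pooled-variance variant would be hard to
justify.

### Spill-over control

Buds sit *on* the tubes, and in the protein channel a strongly enriched tube
is ~10x brighter per pixel than the bud. Two controls keep the two
photometries independent:

* tube integration excludes centerline positions within one bud radius plus
  3.5 PSF sigmas of any bud centroid (at 1 sigma, bud lipid still
  contaminates the faint tube lipid signal by several percent);
* bud integration subtracts a *modeled* image of the flanking tube: the
  per-pixel line intensity is estimated from the trace away from buds,
  deposited continuously along a smoothed centerline with a sub-pixel gap of
  the bud radius, and blurred through the PSF. Sub-pixel gap placement
  matters — half a pixel of misplaced line mass shifts the bud ratio by
  ~20% when the enrichment is strong.

With both controls, simulated fields recover configured enrichments of 1,
1.6 and 13.2 with <5% bias at realistic noise.

## Plateau-plus-exponential kinetics

The clathrin intensity at a kymograph pixel is modeled as a flat plateau
followed by a one-phase exponential rise,

$$F(t) = F_0 \;\; (t \le t_0), \qquad
  F(t) = F_0 + A\,(1 - e^{-(t - t_0)/\tau}) \;\; (t > t_0),$$

with onset $t_0$ and assembly time constant $\tau$. For fixed $(t_0, \tau)$
the model is linear in $(F_0, A)$, so the fitters profile the linear
parameters by ordinary least squares (with $A \ge 0$) and search only the
two nonlinear ones: a coarse grid gives a global start and Nelder-Mead on
$(t_0, \log\tau)$ refines it. For whole kymographs the grid scan reduces to
dense matrix products shared by all pixels, which keeps a 4,000-pixel
kymograph fit under half a minute on one core. The test suite checks the
production fitter against an independent brute-force grid oracle (SSE within
0.1%).

The full pipeline mirrors the experimental procedure:

1. **Dead time.** The flow cell delays protein arrival; the mean off-tube
   (solution) fluorescence is fitted with the same plateau-rise model and
   frames before the fitted onset are discarded, re-zeroing the clock at
   arrival.
2. **Kymographs.** Each tube centerline is sampled over a 3-px band normal
   to the trace (capturing the PSF-spread signal; results are insensitive to
   width 1 vs 3), minus a per-frame background taken as the median over
   pixels outside a 5-px dilation of the object mask. Per-frame correction
   also removes the rising bulk signal, so focus-free rows sit near zero.
3. **Per-pixel fits, R² filter.** Every row is fitted; fits with
   $R^2 < 0.8$ are discarded ($R^2 = 1 - SS_{res}/SS_{tot}$ about the trace
   mean; traces with $SS_{tot} = 0$ are rejected). A pipeline-level
   amplitude gate (fitted $A$ at least 5 background-noise SDs) additionally
   rejects low-contrast baseline wobble that can pass the $R^2$ filter on
   trend alone.
4. **Deduplication.** A focus spans several adjacent pixels; contiguous
   retained pixels (gaps of at most 1 px bridged) collapse to one event
   carrying the member fit with the smallest onset, ties broken by higher
   $R^2$, then lower position. Note a small inherent bias of this rule:
   among correlated per-pixel fits, the smallest fitted onset tends to pair
   with a slightly long $\tau$ (onset and time constant trade off along the
   rise), which inflates the recovered geometric mean by ~1-2%. The rule is
   retained because it is the standard way to avoid oversampling.
5. **Summary.** Assembly time constants are long-tailed, so they are
   summarized by the geometric mean with a t-based 95% CI in log space:
   $\exp(\bar{x} \pm t_{0.975,n-1}\, s/\sqrt{n})$, $x = \ln\tau$. A
   bootstrap CI would be a reasonable alternative; the log-space t-interval
   was chosen as the simplest method consistent with reporting a geometric
   mean and CIs.

Whether pixel traces should be smoothed before fitting is an open choice;
the default fits raw traces, since a 3-frame temporal median would bias
short time constants at a 5 s frame interval. The plateau level is left
free rather than pinned to the first frames.

## Foci detection and the resolution correction

Foci are detected as local maxima of the background-corrected 3-px band
profile along each trace, requiring topographic prominence *and* absolute
height of at least 5 background-noise SDs (pure-noise prominences can reach
5 SDs over hundreds of positions; heights do not) and a minimum separation
of one PSF FWHM. Density is counted at the frame nearest 300 s after the
dead time, the fixed-incubation convention that precedes large-scale focus
merging.

Counting is resolution-limited: two foci closer than the PSF merge, thinning
a Poisson process by a dead zone around every detected focus. At the
wild-type rate (0.4 foci/um) this biases the raw density low by ~15%, which
would make the estimator unusable for rate comparisons. `compute_density()`
therefore also reports a corrected density: the dead-zone radius $r$ is
estimated from the smallest observed nearest-neighbor spacing (bounded below
by the detector's minimum separation) and the underlying rate solves
$\lambda e^{-\lambda r} = \lambda_{obs}$ — the standard hard-core thinning
inversion. The raw count-per-length density is reported alongside. On
simulated fields the corrected estimator is unbiased within ~2% at the
wild-type rate; the correction is negligible (<2%) at sparse rates such as
the clathrin-binding-site mutants.

## One-site binding and SEM geometry

Titrations are fitted to $F = F_{max}[P]/(K_d + [P])$ by Levenberg-
Marquardt with $K_d > 0$, starting from $F_{max,0} = \max F$ and the
half-saturation concentration by linear interpolation. No ligand-depletion
correction is applied (the underlying model is the simple hyperbola), and
fitting in $\log K_d$ agrees with the linear parameterization to $10^{-4}$
relative. The replicate column is carried but pooled — per-template means
versus pooled pixels give the same estimate up to weighting.

SEM measures object plus coating, so each coating layer (streptavidin
4.4 nm, sputtered gold 4 nm) is subtracted twice — once per side of a
diameter. Values are reported raw (63.3 - 16.8 = 46.5 nm) and half-up
rounded (47 nm), since nominal diameters are conventionally quoted with 0.5
rounded away from zero.

## The simulator: what it emulates, and what it does not

Defaults describe the imaging setup of this kind of experiment: 160 nm
pixels (100x objective, 16 um EMCCD pixels), an isotropic Gaussian PSF of
sigma 110 nm (~0.21 lambda/NA at 600 nm, NA 1.4), 5 s frame interval for
kinetics. Membrane is deposited as expected intensity proportional to local
surface area (tubes as cylinders, buds as projected spherical shells with
their characteristic edge-bright profile), blurred by a pixel-integrated
separable Gaussian applied by direct convolution (an FFT convolution leaves
numerical ripple across the background that corrupts noise-floor
estimates), then subjected to Poisson shot noise plus Gaussian read noise
(SD 3 a.u.). The EMCCD excess-noise factor is not modeled separately; it is
absorbed into the photon scale. Tubes are laid out as parallel rows, which
matches flow-extruded templates aligned with the flow; the deposition
machinery accepts arbitrary segment orientations.

Assembly movies add a uniform solution signal that stays flat until the
configured dead time (30 s default) and then rises exponentially (tau 10 s),
plus foci placed by a spatial Poisson process along the tubes (0.4/um
default, or an exact count when specified). Each focus follows the
plateau-exponential model with $\tau$ lognormal (geometric mean 74 s,
geometric SD 1.8 — matching the long-tailed single-event statistics of
clathrin assembly), onset = dead time + an exponential nucleation delay
(mean 20 s; no nucleation-time distribution is established for this system,
so the simplest memoryless choice is used), and a constant plateau flux
(2000 a.u.).

Features deliberately *not* modeled, and what that implies for how far the
tests generalize: photobleaching (would bias $\tau$ upward on real data),
illumination nonuniformity (motivates the per-field normalization but is
not simulated), focus lateral mobility and merging dynamics (the R² filter
is how the experimental analysis rejects moving foci; simulated foci are
static), membrane mechanics and tube extrusion hydrodynamics, and drift.
Passing tests therefore demonstrate correctness of the estimators under the
stated optical and noise model, not robustness to every instrumental
artifact of real data.

## Numerical choices and degenerate inputs

* **Thresholding.** Object masks use background median + 4 robust SDs; on
  noiseless synthetic images the MAD degenerates, so the noise scale is
  floored at 1% of the dynamic range.
* **Bud sizing.** The moment-based equivalent diameter solves
  $\mathrm{Var} = R^2/3 + \sigma_{PSF}^2$ for a spherical shell, with
  Sheppard corrections (2/12 px²) for pixel binning of the photometry and
  the pixel-integrated PSF kernel; signed (unclipped) weights make the
  moments noise-unbiased, and the flanking-tube profile is subtracted first.
* **Coordinates.** 1-based row/column indices throughout, the R convention;
  lengths in um, diameters in nm, times in s.
* **Fit failures.** A pixel trace on which the optimizer fails is returned
  flagged invalid with $R^2 = 0$ rather than raising, so noise-only pixels
  flow through and are filtered; the dead-time estimator, by contrast,
  raises "no arrival detected" on flat traces because nothing downstream is
  meaningful without an arrival.
* **Determinism.** Simulators reseed from the configuration, so identical
  config + seed gives bit-identical movies; the workflow runner derives
  per-stage seeds from a single master seed by a fixed affine map.

## Problem sizes

The validation suite runs the full pipelines at the study's operating
points: a 17-tube/15-bud field (220 x 256 px) for ratiometry at enrichments
13.2 and 1.6; a 16-tube movie (280 x 256 px, 120 frames at 5 s) carrying
118 foci for kinetics; and ~1200 um of simulated tube for the foci-density
rate. Property checks (unbiasedness, Poisson statistics, oracle
equivalence, coverage) use reduced replicate fields sized so the whole
suite completes in a few minutes while keeping each check's Monte-Carlo
error well below the tolerance it asserts.
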