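---
title: "Methods: single-molecule tracking and stripe-recruitment quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-molecule tracking and stripe-recruitment quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sptrack)
```

sptrack quantifies how strongly a nuclear protein is loaded onto
chromatin, from two kinds of live-cell recordings: HILO
single-molecule movies, from which it estimates the fraction of
molecules that are chromatin-bound, and confocal laser-microirradiation
series, from which it quantifies recruitment to a damaged stripe.
Both analyses are paired with a ground-truthed simulator so every
stage can be validated against known parameters. This vignette
documents the models, the defaults and their rationale, the numerical
choices, and what the validation does and does not establish.

## The single-molecule pipeline

### Motion model and the apparent diffusion coefficient

Molecules are modeled as a two-state ensemble: a chromatin-bound
population with a small diffusion coefficient (default
$D_b = 0.02\ \mu m^2/s$, residual constrained wobble) and a freely
mobile population (default $D_m = 0.5\ \mu m^2/s$, the mode observed
for a nucleoplasmic protein of this size). For 2-D Brownian motion
with frame interval $\Delta t$, each per-axis per-frame displacement
is $\mathcal N(0,\, 2D\Delta t)$ and the lag-1 mean squared
displacement satisfies $\mathbb E[\mathrm{MSD}] = 4D\Delta t$. The
per-track estimator is deliberately the single-lag form

$$\hat D = \frac{\mathrm{MSD}}{4\,\Delta t},$$

the mean over a track's single-frame steps of the squared
displacement, divided by $4\Delta t$. No multi-lag MSD fitting is
performed: with short tracks (a handful of steps) the lag-1 estimator
has well-characterized sampling behavior, which we exploit below.
Displacements that span a tracker-bridged gap (two frames) are
excluded from the mean rather than rescaled, keeping the estimator an
unbiased lag-1 quantity; tracks whose every step spans a gap carry no
lag-1 information and are dropped (and counted) by `spt_diffusion()`.

With independent localization error of standard deviation $\sigma$
per axis, each measured displacement gains variance $2\sigma^2$ per
axis, so

$$\mathbb E[\hat D] = D + \sigma^2/\Delta t \equiv D_{\mathrm{eff}},$$

and for a track with $n$ single-frame steps
$\hat D \sim D_{\mathrm{eff}}\,\chi^2_{2n}/2n$ (each step contributes
two squared Gaussian axes). This closed form is the package's
calibration oracle: `expected_bound_fraction()` evaluates the exact
probability that a track of given $n$, $D$ and $\sigma$ falls at or
below the classification threshold, and the test suite checks the
simulated estimator against it. The form treats consecutive steps as
independent; localization noise induces a small negative correlation
between neighboring displacements (their squares correlate only at
order $(\sigma^2/(2D\Delta t + 2\sigma^2))^2$, about $2\times10^{-3}$
at the defaults), which is negligible at the tested scales.

A track is classified **bound** when $\hat D \le 0.3\ \mu m^2/s$
(inclusive) and **mobile** otherwise; the per-cell **bound fraction**
is the fraction of retained tracks classified bound. Bound fractions
are computed per cell and then compared across conditions with a
fixed-effects one-way ANOVA on the per-cell values
(`compare_conditions()`), matching a design of a few cells per
treatment with thousands of tracks each. Pooling tracks across cells
before classification would discard the cell-level replication that
the ANOVA needs.

### Detection and localization

Spots are detected per frame on a band-pass filtered image: the
difference of two Gaussian blurs, $\sigma_{\text{small}} = 1$ px and
$\sigma_{\text{large}} = 3$ px. A diffraction-limited spot at
0.096 um/px has a PSF standard deviation of roughly 1-1.5 px, so the
narrow scale matches the spot while the wide scale removes slowly
varying background; a flat field maps to zero. Candidates are local
maxima (8-neighborhood) exceeding the frame's filtered
mean $+ k\cdot$SD with $k = 5$ by default — at Gaussian-tail rates
this keeps false positives per 256x256 frame well below one even
before non-maximum suppression. Maxima closer than the ROI side
$K = 7$ px to a stronger maximum are suppressed; $K = 7$ covers about
$\pm 3\sigma_{\mathrm{PSF}}$. Candidates whose ROI would cross the
image edge are dropped, not padded (their count is recorded).

Sub-pixel localization uses the phasor method: the phase of the
first-harmonic discrete Fourier coefficient of the ROI along each
axis,

$$F_x = \sum_{r,c} I(r,c)\, e^{-2\pi i c/K},
\qquad \hat x = -\frac{K}{2\pi}\arg F_x,$$

referenced to the ROI center and wrapped into $(-K/2, K/2]$. The raw
ROI is used without apodization. On noiseless pixel-integrated
Gaussian spots across a 9x9 grid of sub-pixel offsets in
$[-0.45, 0.45]$ px the phasor estimate agrees with the true position
and with a least-squares Gaussian fit to better than 0.05 px RMS (the
fit is used only as a test oracle, never in the pipeline). A uniform
background contributes nothing to the first harmonic, so the
estimator is offset-robust.

Coordinates are 0-based pixel-center coordinates in pixels;
micrometer coordinates are $(x_{\mathrm{px}} + 0.5)\cdot$
`pixel_size`, which places localizations in the same corner-origin
continuous frame the simulator's ground truth uses. Only positions
are affected, never displacements, so all diffusion quantities are
independent of this convention.

### Linking

Localizations are linked frame to frame when they fall within a
circular search radius (default 8 px) of a track's last position. A
memory of one frame lets a track survive a single missed detection or
blink; the gap-spanning link uses the same 8 px radius measured from
the last seen position (the radius is deliberately not inflated for
gaps — a conservative choice the data model makes explicit). Within
each frame, the assignment of localizations to active tracks is the
one-to-one matching that maximizes the number of links and, among
those, minimizes the total squared distance; it is solved exactly by
branch-and-bound within each connected component of the feasibility
graph, with lexicographic tie-breaking for determinism. Greedy
nearest-neighbor linking is order-dependent and was rejected; the
test suite pins the semantics to an exhaustive enumeration oracle on
one hundred random scenes. Tracks with fewer than 4 linked steps
(fewer than 5 localizations) are discarded before analysis.

### The synthetic movie generator

`simulate_trajectories()` + `render_movie()` emulate the recordings
the pipeline expects: 256x256 px at 0.096 um/px and 20 ms/frame by
default, molecules confined to a nuclear mask (default: a centered
disk of radius 0.35 x image size, the scale of a ~10 um nucleus in
this field of view), assigned bound/mobile once per recording,
stepping as Brownian motion and reflected at the mask boundary
(mirroring the offending step about the previous position; if no
reflected candidate lands inside the mask the molecule holds its
position for that frame — reflection preserves per-axis step
magnitudes, so squared displacements are unaffected). Fluorophores
blink as a two-state per-frame Markov chain started from its
stationary distribution; photobleaching is not modeled.

Rendering integrates an isotropic Gaussian PSF over each pixel via
error-function differences (not center sampling, which would bias the
sub-pixel localization tests), adds a uniform expected background,
and draws every pixel from a Poisson law — equivalent to a total spot
intensity that is Poisson with the stated mean, thinned over pixels.
Photon-budget and blinking defaults are assumptions, since dye
photophysics under the relevant excitation are not published for this
setup: 1000 detected photons per spot per frame and 5 background
photons per pixel give a peak-SNR regime where detection is nearly
perfect — deliberately, so that pipeline tests probe the analysis
rather than the camera model; `k_off = 0.05`/`k_on = 0.5` per frame
give ~20-frame on-times and a 91% duty cycle, exercising the
tracker's memory without fragmenting most tracks. The generator does
not model EM-gain excess noise, chromatic or astigmatic PSFs, defocus
loss in z, drift, or a heterogeneous background; consequences for
interpretation are discussed under Limitations.

The generator also has a rendering-free path, `truth_to_tracks()`,
which emits the true positions of emitting frames with independent
Gaussian localization error (`loc_sigma`, default 0.03 um). This is
the path used for estimator-calibration tests, where detection and
linking would only add confounds.

Determinism: a configuration seed fixes the trajectory stream, and
the renderer re-seeds at `seed + 1` (after forcing its arguments) so
photon noise is decoupled from trajectory randomness; identical
configurations reproduce movies bit-identically.

## Stripe-recruitment quantification

For each cell and timepoint, three hand-drawn regions are averaged:
the irradiated stripe ($A_x$), the rest of the nucleus avoiding the
stripe ($C_x$), and an extranuclear background ($B$). Relative
recruitment is

$$S_x = \frac{A_x - B}{C_x - B},$$

which is invariant under affine rescaling of the image (gain and
offset cancel) and requires $C_x > B$; the package refuses to divide
otherwise. Because the chromatin environment is not uniform, the
pre-irradiation stripe is not exactly at parity, so each series is
normalized by subtracting $S_x(t_1) - 1$ from every timepoint —
an additive shift that makes the first timepoint exactly 1 and
preserves all differences. Normalization is applied per cell by
default so cells from different fields remain comparable; a
`normalize_mean` mode shifts the cross-cell average instead, for the
variant where only the field-level average is anchored. Curves are
aggregated across cells as mean with SEM $=$ sample SD (n-1
denominator) $/\sqrt{n}$; a single cell reports SEM 0 with a warning.

The stripe simulator draws a nucleus of uniform baseline brightness
on a darker background and raises the stripe after irradiation along
a single-exponential saturation,
$\text{baseline} + \text{amplitude}\,(1 - e^{-\text{rate}\,t_{\text{post}}})$ —
the simplest saturating form consistent with the shape of observed
recruitment curves; no kinetic model is fitted to real data anywhere
in the package. Gaussian pixel noise is added and counts are rounded
and clamped at zero (with default brightness levels, clamping is
never active in practice).

### Calibrating the recovery check

Parameter recovery is verified by comparing the measured normalized
curve against the generator's true curve within three standard
errors. With a handful of cells the sample SEM itself is a noisy
quantity (4 degrees of freedom at $n = 5$), and per-cell
first-timepoint anchoring gives all timepoints of a cell a shared
offset, so a literal 3 x sample-SEM band rejects a correct pipeline
a few percent of the time at any noise level. The checks therefore
bound deviations by three times the larger of the sample SEM and the
closed-form SEM implied by the generator's own noise model
(`stripe_theoretical_sem()`: delta-method propagation of per-region
mean variance $(\sigma^2_{\text{noise}} + 1/12)/n_{\text{px}}$,
including the rounding term and the anchor timepoint's contribution).
The closed-form SEM is the exact quantity the sample SEM estimates,
so this calibrates the yardstick without loosening the band.

## Problem sizes used in validation

The validation suite chooses sizes that make each property sharply
testable: localizer accuracy on an 81-point noiseless offset grid;
tracker semantics on 100 random small scenes against exhaustive
enumeration; estimator calibration on 10,000 rendering-free tracks of
20 steps ($D = 0.5\ \mu m^2/s$, $\sigma = 0.03$ um); mixture
recovery on 6,000 tracks at a bound fraction of 0.4; and an
end-to-end contrast of bound fraction 0.2 versus 0.5 with three cells
per condition and over 1,000 retained tracks per cell, run through
the full image pipeline. For the contrast, each simulated cell pools
six independent acquisition segments (250 frames, 40 molecules,
192x192 px) rather than one long movie of a fixed cohort: a real
recording samples a large nuclear pool of labeled molecules over
time, whereas a persistent cohort of ~30 molecules would make the
cell-level realized bound fraction binomially noisy
(SD $\approx 0.07$) regardless of how many tracks it yields. Pooled
segments restore a realistic number of distinct molecules per cell.

## Known limitations

- The bound/mobile split is a hard threshold on a noisy per-track
  estimate; near-threshold tracks are misclassified at rates the
  $\chi^2$ closed form predicts, and short tracks are attenuated
  toward the mixture's other component. The package reports the
  closed-form expectation so users can see the attenuation rather
  than mistake it for biology.
- Linking uses distance only; no motion model, merging or splitting.
  At high densities identity switches between a bound and a passing
  mobile molecule inflate the apparent mobility of bound tracks.
- The simulator's uniform background, isotropic in-focus PSF and
  absence of photobleaching mean that passing its tests demonstrates
  correctness of the analysis, not robustness to every imaging
  pathology of real data.
- Stripe masks are taken as given (hand-drawn, possibly
  per-timepoint); no automated segmentation or bleaching correction
  is provided.

## A worked example

```{r example, fig.width = 6, fig.height = 4}
cfg <- spt_sim_config(n_frames = 300, image_size = 96,
                      n_molecules = 15, f_bound = 0.4, seed = 2)
movie <- render_movie(simulate_trajectories(cfg), cfg)
locs <- localize_movie(movie)
tracks <- filter_tracks(build_tracks(locs))
fit <- spt_diffusion(tracks, frame_interval = cfg$frame_interval)
fit
plot(fit)
```

At this miniature scale the recovered bound fraction deviates
noticeably from the configured 0.4: only 15 molecules are drawn, so
the cohort's realized bound fraction is itself binomial
(SD $\approx 0.13$), and near-threshold tracks are misclassified at
the rates the $\chi^2$ form predicts.
`expected_bound_fraction()` quantifies the misclassification
component for any track length; the cohort effect shrinks with the
number of distinct molecules, which is why the validation contrast
pools segments (see above).
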