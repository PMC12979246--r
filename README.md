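# sptrack

Live-cell single-molecule tracking and laser-stripe recruitment
analysis for chromatin-binding proteins, with a ground-truthed
simulator for end-to-end validation.

Proteins such as DNA-repair factors change their nuclear mobility
when they engage chromatin. Two standard readouts quantify this:

1. **Single-particle tracking (SPT).** HILO movies of sparse,
   dye-labeled molecules (e.g. 256 × 256 px, 0.096 µm/px, 20 ms/frame,
   thousands of frames) are reduced to per-molecule trajectories.
   Each track's lag-1 mean squared displacement gives an apparent
   diffusion coefficient

   *D* = MSD / (4 Δt),

   and a track is called **bound** when *D* ≤ 0.3 µm²/s and
   **mobile** otherwise. The per-cell *bound fraction* — the fraction
   of tracks with *D* ≤ 0.3 µm²/s — is the summary statistic, and
   conditions are compared by one-way ANOVA on per-cell fractions.
   With per-axis localization error σ the estimator is inflated to
   E[*D̂*] = *D* + σ²/Δt, and for a track of *n* steps
   *D̂* ~ *D*_eff · χ²₂ₙ/2n; the package carries this closed form
   (`expected_bound_fraction()`) so recovered fractions can be judged
   against what classification noise predicts.

2. **Microirradiation-stripe recruitment.** After a laser draws a
   damage stripe in a nucleus, recruitment is scored per cell and
   timepoint as the background-corrected relative stripe brightness

   *Sx* = (*Ax* − *B*) / (*Cx* − *B*),

   with *Ax* the stripe mean, *Cx* the nucleus remainder and *B* the
   background. Series are anchored so the pre-irradiation timepoint
   equals 1 (subtracting *Sx*(t₁) − 1), then averaged across cells
   with SEM = SD/√n.

The pipeline stages — spot detection on band-pass (difference of
Gaussians) filtered frames, phasor (first-harmonic Fourier) sub-pixel
localization, radius-and-memory trajectory linking with exact
minimum-cost frame assignment, diffusion classification, ANOVA, and
stripe quantification — are exposed as composable functions, and a
simulator generates movies with known ground truth (two-population
Brownian motion in a nuclear mask, pixel-integrated Gaussian PSFs,
Poisson photons, two-state blinking; exponential-rise stripe stacks)
so each stage is testable. See the methods vignette
(`vignettes/single-molecule-tracking.Rmd`) for models, defaults and
limitations.

## Worked example

```r
library(sptrack)

cfg    <- spt_sim_config(n_frames = 300, image_size = 96,
                         n_molecules = 15, f_bound = 0.4, seed = 2)
movie  <- render_movie(simulate_trajectories(cfg), cfg)
locs   <- localize_movie(movie)
tracks <- filter_tracks(build_tracks(locs))
fit    <- spt_diffusion(tracks, frame_interval = cfg$frame_interval)
fit
#> Per-track diffusion analysis (lag-1 MSD, D = MSD/(4*dt))
#>   tracks: 113   dt: 0.02 s   bound threshold: D <= 0.3 um^2/s
#>   bound fraction: 0.177   median D: 0.519 um^2/s
```

113 tracks with ≥ 5 localizations survive filtering; the median
apparent D of ~0.5 µm²/s reflects the mobile population, and the
bound fraction deviates from the configured 0.4 at this miniature
scale (15 molecules make the cohort's realized fraction binomially
noisy, and short tracks are misclassified at the χ²-predicted rate —
`expected_bound_fraction(0.4, 0.02, 0.5, 10, 0.02, 0.03)` gives
0.43 for 10-step tracks). `plot(fit)` draws the D histogram with the
0.3 µm²/s threshold.

Stripe quantification on hand-computed numbers:

```r
compute_sx(Ax = 10, Cx = 4, B = 1)        # (10-1)/(4-1)
#> [1] 3
normalize_series(c(1.12, 1.50, 1.80))     # anchor t1 to 1
#> [1] 1.00 1.38 1.68
```

A full simulate → localize → track → diffuse → compare run, driven by
one config and one seed, is `run_pipeline(run_config(...))`; a thin
command-line front end with the same stages lives at
`inst/scripts/sptrack` (subcommands `simulate-spt`, `simulate-stripe`,
`localize`, `track`, `diffuse`, `compare`, `stripe`, `run`).

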