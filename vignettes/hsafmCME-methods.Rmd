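---
title: "Quantifying clathrin-mediated endocytosis in hybrid HS-AFM/confocal movies"
author: "hsafmCME"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying clathrin-mediated endocytosis in hybrid HS-AFM/confocal movies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hsafmCME)
```

## The measurement problem

During clathrin-mediated endocytosis (CME) a patch of plasma membrane
invaginates into a coated pit of 150–400 nm aperture, stays open for tens to
hundreds of seconds, and then closes as the vesicle pinches off. A
tip-scanning high-speed AFM records the membrane topography of a living cell
(here a 6.0 × 4.5 µm² scan area at 18.75 nm/pixel, one frame every 10 s)
while a confocal scanner images fluorescently tagged proteins — clathrin,
epsin, dynamin, actin, caveolin — in the same field. The two instruments
share no coordinate frame and no clock; registration rests on the
autofluorescence of the parked cantilever tip, whose spot defines the origin
of a common frame into which the AFM scan corners are placed.

This package implements the complete quantification chain for such movies —
registration, pit detection and tracking, section-profile morphometry,
fluorescence phase segmentation, closing-motion classification, and
drift-corrected diffusion estimation — together with a synthetic-data
generator that emulates the imaging physics well enough that every estimator
can be validated by parameter recovery. Real acquisitions of this kind are
not publicly archived, so the generator is a first-class component: its
defaults *are* the study conditions, and the test suite asserts that the
estimators recover them.

## The synthetic acquisition model

**Geometry.** Each pit is a radially symmetric raised-cosine depression,
$z(r) = -d\,\cos^2\!\big(\pi r / 2a\big)$ for $r < a$, with aperture radius
$a$ and depth $d$ (default 30 nm — the papers in this field do not print a
depth, and 30 nm makes pits unambiguous against a few nm of membrane
roughness while staying shallow relative to their width). The raised cosine
is smooth, has an unambiguous baseline crossing at $r = a$, and approaches
the baseline tangentially — the property that makes edge measurement
genuinely hard, as on real AFM profiles. Capping swellings are positive caps
of the same form, with diameter ~378 nm and height ~38 nm drawn per event
(SDs 62 and 10 nm).

**Kinetics.** CCP lifetimes are drawn from $40 + \Gamma(k, \theta)$
truncated at 330 s with $k = 0.4345$, $\theta = 106.93$; these constants
were solved so the truncated distribution has mean 81 s and SD 55 s exactly.
(No truncated normal on [40, 330] can reach SD 55 at mean 81 — the
distribution must be right-skewed, which also matches the short-lifetime
bias seen in CME.) The lifetime splits into growing / stable / closing
phases, with closing uniform on 20–50 s and the remainder divided between
growing (≥ 40 s when possible) and stable (≤ 260 s). Caveolae stay open for
the whole movie.

**Closing motions.** Labels are drawn from the condition mixture — untreated:
54.9% capping, 20% two-step, 10% re-opening, remainder plain; presets
re-weight these for the cytochalasin-B, CK666, jasplakinolide and dynamin-2
knockdown conditions. Capping and re-opening are mutually exclusive (the
inverse relation seen in the cross-tabulation); two-step co-occurs freely.
Two-step events decline to a plateau diameter ~N(120, 10) nm held for
10–40 s before closure; plain/sudden closures decline to no less than
max(200, a_max/2) nm before vanishing, so that the defining contrast of the
two-step motion — entry into the small-aperture band — is a property of the
event, not of measurement noise. Re-opening events close, stay closed for a
uniform 10–70 s gap (during which the clathrin signal drops to a retention
fraction ~N(0.39, 0.18) of its maximum), and re-open displaced by a uniform
13–113 nm; the gap is carved out of the drawn lifetime so that the tracked
lifetime (first detection to final closure, gap included) keeps its mean.

**Motion.** The trajectory sampler draws isotropic Gaussian steps with
per-axis variance $2 D \Delta t$ plus a drift vector; it is the model under
which the MSD slope is $4D$, and it is what the diffusion-recovery analyses
use, at the class mobilities $D_{CCP} = 7.3\times10^{-9}$ and
$D_{cav} = 2.1\times10^{-9}$ cm²/s. Inside rendered movies, pit wander is
confined (radial reflection into a 75 nm disc): at
$7.3\times10^{-9}$ cm²/s a free 10-s step is ~3.8 µm RMS per axis, which
would carry a pit out of the 6.0 × 4.5 µm² field within a frame, whereas
live-cell observations show pit centroids wandering by tens of nm over
100 s. The confinement radius emulates that corralled motion; it is a
generator parameter, not part of the free-diffusion analyses.

**Imaging physics.** The background is a static Gaussian random field
(RMS 2 nm, correlation length 100 nm — the membrane texture persists between
frames) plus 1 nm white per-frame sensor noise. The finite tip images the
surface by grayscale dilation with a spherical cap (default radius 10 nm, so
that the instrument-convention correction of subtracting the tip *diameter*
maps the measured 150–400 nm range onto 130–380 nm). Tip skips replace 1–2
consecutive scan rows (≈ 37 nm at 18.75 nm/pixel) with the previous row plus
an offset; amplitude steps rescale a frame's relief. Heights are quantized
to a 0.01 nm grid, emulating the z-DAC and making TIFF round trips exact.
Fluorescence channels use a Gaussian PSF (σ = 106 nm ≈ 250 nm FWHM) on an
83 nm optical grid with Poisson photon noise (peak ~200 photons, background
20) and Gaussian read noise (σ = 2 counts); the confocal scan starts a
uniform [0, Δt) lag after the AFM scan, because the two controllers are not
synchronized.

Note one deliberate asymmetry: dilation by a physical tip *narrows* a
depression, yet the instrument convention subtracts the tip diameter from
the measured width. The generator applies true dilation; `tipCorrect()`
follows the instrument arithmetic. The two are not reconciled — at the
default 10 nm tip radius the dilation footprint is smaller than one pixel,
so the issue is documented rather than material.

## Measurement operators

**Section profiles** are bilinear resamplings of a height frame along a line
through a feature center at one-pixel spacing. `measureDiameter()`
implements the classical edge walk: baseline = mean of the two flank medians
(outer 25% per side), edge = first sample within ε (1 nm) of baseline
walking outward from the extremum. On noiseless profiles this recovers
raised-cosine apertures to one pixel. On noisy frames it is fragile, because
the raised-cosine rim meets the baseline tangentially: any correlated dip
just outside the rim extends the walk. The production estimator
`sectionDiameter()` therefore (i) works on frames with the static texture
removed (per-pixel temporal median subtraction — pits are transient, texture
is not; where the background is itself deep, as under a persistent caveola,
the raw frame is used), (ii) locates the rim per side by extrapolating the
interpolated crossings at two depths $e$ and $4e$ below baseline to the
tangential crossing (for any smooth rim, locally quadratic:
$a = 2 r_1 - r_2$), and (iii) takes twice the median of the per-side radii
over four section angles, minus half a pixel of resampling support widening.
This is sub-pixel, shape-robust, and insensitive to directional outliers;
on noiseless pits it is unbiased within one pixel across 150–400 nm.

**Swelling height** is the profile maximum minus the mean of the two basal
medians, medianed over four angles. **Pit area** follows the morphological
cascade: 3×3 median filter, black top-hat with a ~20 px disc, opening–closing
with a ~6 px disc, threshold at half the maximum response, area =
suprathreshold pixels × pixel area. EBImage disc brushes must be odd-sized,
so the printed 20 px and 6 px become 19 px and 5 px. With the half-max
threshold the suprathreshold mask of a raised-cosine pit is its half-depth
contour (≈ 25% of the aperture disc), so the area-tracks-diameter check is
meaningful only for flat-bottomed (disk) depressions, and that is how it is
tested.

**Detection** removes a running-median baseline (750 nm window), thresholds
10 nm below it, splits merged regions by watershed, and confirms candidates
by a preliminary section diameter ≥ 60 nm (applied to the profile estimate,
not to the thresholded-mask width, so that 80 nm caveolae — whose
suprathreshold mask is only ~50 nm wide at 30 nm depth — remain detectable).
**Tracking** is greedy nearest-neighbour linking within 250 nm per frame,
with a gap-closing pass across ≤ 7 missing frames within 120 nm — the
re-opening geometry (gaps 10–70 s, displacement ≤ 113 nm). Greedy rather
than global assignment is adequate at these pit densities (a few concurrent
pits per scan area) and is a documented limitation.

**Closing-motion classification.** Capping ⇔ a covering swelling (positive
feature ≥ 150 nm wide and ≥ 20 nm high within 1.5 × the last pit diameter,
whose footprint overlaps the former pit centroid at or after closure).
Two-step ⇔ a terminal run of small-aperture frames before final closure
preceded by ≥ 2 large-aperture frames. The nominal class boundary is 150 nm
(the CCP minimum); because the edge of a feature is only defined to one
sample pitch, the implemented boundary carries half a pixel of guard band
*above* 150 nm, and the terminal run tolerates one isolated large reading.
Re-opening ⇔ a closed-gap interval of 1–7 frames (the linker already bounds
the displacement). Plain closures are the residual class.

## Phase segmentation and its identifiability limit

The stable phase of a max-normalized clathrin trace is the earliest run of
more than 4 frames whose 3-frame-smoothed central-difference slope lies in
[−0.05, +0.1] per frame; growing and closing are the periods before and
after. Two consequences of this definition deserve emphasis. First, a trace
bounded by 1 cannot sustain a slope above 0.1/frame for more than ~10
frames, so the *onset* of a stable phase is only localizable when the rise
to plateau takes ≲ 6–8 frames; slower rises enter the band from the start
and the rule, applied faithfully, places the stable phase early. Second,
3-frame smoothing flattens the short final rise to the peak, so the slope
rule registers the end of the stable phase at the peak frame. The generator
therefore records, as trace-level truth, the construction knots with the
stable end at the peak frame, and the recovery properties are asserted on
the identifiable regime (rise ≤ ~60 s, stable ≥ 5 frames): boundaries within
1 frame on clean traces and within 2 frames at the default trace noise for
≥ 90% of events. Edge smoothing shrinks the window rather than padding; the
run search is restricted to frames above 5% of the trace maximum so noise
floors cannot seed a run.

Event anchors come from the AFM: invagination = first frame of the first
≥ 2-frame detection run; closure = first frame with no detection after the
last one; both at the 10 s frame granularity. Appearance/disappearance of a
channel require 2 consecutive frames above (below) background mean ± 3 SD
from a local annulus. With 10-s sampling, cohort timing means are recovered
to within about one frame; test tolerances are therefore
max(2 SE, one frame).

## Drift and diffusion

The ensemble drift estimator averages, for every consecutive frame pair,
the displacement of all tracks present in both frames, and accumulates the
increments; the first-vs-last variant reproduces the classical
initial-vs-final average displacement of all pits. Because randomly
diffusing pits have zero mean displacement, what survives the average is
stage drift. MSDs are time-averaged per track over all detection pairs at
each lag (gap pairs excluded), pooled across tracks with ≥ 5 detections
weighted by pair counts, and fitted by zero-intercept least squares over
lags 1–4 (the tracks are short — a mean lifetime of 81 s is ~8 frames — so
longer lags carry little information); $D$ = slope/4, converted exactly at
1 cm² = 10¹⁴ nm². Subtracting a per-frame ensemble mean of $n$ tracks
removes $1/n$ of the random motion along with the drift, a ~0.5% downward
bias at $n = 200$ — far inside the 15% recovery tolerance.

One scale consequence of the class mobilities: the magnitude of the
ensemble-mean net displacement of $N$ drift-free trajectories has
expectation $\sqrt{\pi/2}\,\sigma$ with
$\sigma = \sqrt{2 D \Delta t (T-1)/N}$ — about 500–700 nm at
$D = 7.3\times10^{-9}$ cm²/s, 40 frames, $N = 2000$. "Null" therefore means
*consistent with zero within 3 SE*, which the test asserts; the absolute
number is set by the mobility, not by estimator quality.

## Problem sizes and runtime choices

The validation cohorts are: 2,000 trajectories for the drift null; 200
tracks per class for diffusion recovery; 50 capping and 50 two-step events
(two 25-event movies each, tip radius 0, default noise) for swelling and
plateau geometry; 300 events in ten 30-event movies for the untreated
capping percentage; and the first seven of those movies (~210 events) for
the lifetime recovery. Events are placed so they complete within the movie
(placement is independent of the drawn lifetime, so no length bias is
introduced) — censoring is then structural (caveolae, edge-born tracks)
rather than accidental. A 30-event, 90-frame movie takes ~15 s to render
and ~10 s to analyze on one core.

## What passing does and does not show

The generator emulates: pit geometry and lifecycle kinetics at the study's
printed values, confined pit wander, stage drift, tip dilation, scan-line
artifacts, sensor noise and quantization, PSF + shot/read noise, and the
AFM/confocal scan lag. It does not emulate: clathrin lattice texture,
ruffles or cytoskeleton relief beyond the stationary background field,
z-drift, tip wear or contamination, spatially varying noise, out-of-focus
fluorescence, or any mechanistic coupling between protein amounts and
membrane shape (traces are phenomenological piecewise-linear courses).
Recovery on these data therefore demonstrates internal consistency of the
estimators under the stated imaging model — not performance on real movies,
where detection thresholds and the swelling-coverage criterion would need
re-validation.

## Worked example

```{r example, eval = FALSE}
cfg <- simulationConfig(nEvents = 20L, nFrames = 90L, seed = 1L)
bundle <- generateDataset(cfg)
res <- runAnalyze(bundle)
res$motionSummary$percentages
res$meanLifetime
res$diffusion$CCP
report <- runEvaluate(res, bundle)
report$detectionPrecision
```
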