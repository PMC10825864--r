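---
title: "Models and methods behind aieclust"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind aieclust}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aieclust)
```

## What the package models

Membrane receptors such as HER2 organize into nanoscale clusters, and an
aggregation-induced-emission (AIE) antibody conjugate can read that
organization out on an ordinary widefield microscope: the fluorophore is
dark unless its intramolecular motion is restricted by a second
fluorophore within a narrow distance window, so emission reports receptor
*proximity*, not receptor *amount*. A conventional dye on the same
antibody reports amount only. The contrast between the two channels is
what turns a plain fluorescence plate assay into a cluster assay — for
example, for following how an anti-HER2 therapeutic disperses clusters
over dose and time while total receptor content stays constant.

`aieclust` provides the full synthetic counterpart of such an experiment:
a generative model of receptor organization, an optical forward model,
and the quantification chain used on real images (cell-area segmentation,
masked mean intensity, SNR, Pearson colocalization, normalized
dose–response tables with significance annotation). Because every stage is
simulated, every downstream statistic can be validated against known
ground truth.

## Receptor organization

**Footprints.** A cell footprint is a star-shaped polygon: a circle of
`mean_radius` (default 5000 nm) radially modulated by a band-limited
harmonic perturbation of amplitude `irregularity` (default 0.25). The
radial function is single-valued and positive, so the polygon is simple by
construction. Coordinates are continuous nanometres with the origin at the
bounding box's lower-left corner.

**Clustered membranes** follow a Thomas process: Poisson cluster centres
(`kappa`, default 0.4 parents/µm²) with Poisson(`mu`, default 25)
offspring scattered isotropically with `sigma` = 30 nm. Offspring
falling outside the footprint are discarded. A hard-core distance of 2 nm
is enforced by sequential rejection — two antibody-bound receptors cannot
coincide, and the hard core also keeps the lower edge of the AIE window
meaningful. These defaults are illustrative: no measured cluster sizes or
densities exist for the cell lines in question, so the values were chosen
once to give a few hundred clustered receptors per cell, and the tests
treat them as fixed study conditions rather than tunable dials.

In the end-to-end experiment, a clustered membrane is the superposition
of the Thomas component and a dispersed (CSR) pool of
`background_intensity` = 15 receptors/µm². This reflects the biology of an
overexpressing line — abundant uniform expression *plus* clusters — and it
matters practically: the dispersed pool is what makes the cell one
contiguous object in the conventional-dye channel, which the segmentation
stage relies on to delineate "the cell area" rather than individual
cluster blobs.

**Dispersed membranes** (the low-expression comparator) are a homogeneous
Poisson pattern at `csr_intensity` = 15 receptors/µm², hard-core thinned.

**Disruption.** Treatment relocates each clustered receptor independently
to a uniform position in the footprint with probability

$$p(D, t) \;=\; p_{\max}\,\bigl(1 - e^{-t/\tau}\bigr)\,
  \frac{D^{h}}{D^{h} + \mathrm{EC}_{50}^{h}},$$

with defaults `p_max` = 0.8, `EC50` = 1 µg/mL, `h` = 1, `tau` = 8 h. The
Hill factor stands for saturating target occupancy, the exponential
factor for first-order approach to the treated steady state; neither is a
fitted kinetic model, both are the simplest forms with the right
qualitative shape. Receptor count is conserved exactly — the drug
disperses clusters, it does not remove receptors — which is precisely why
the conventional channel should stay flat under treatment.

## Emission and image formation

A receptor is labeled with probability `labeling_efficiency` (default
0.9). Under the AIE rule a labeled fluorophore is emissive iff at least
one other labeled fluorophore lies within the closed window
[`d_min`, `d_max`] = [2.13, 6.62] nm, the ground-state geometry limits of
the dye pair. Emission is binary (on/off at `unit_brightness` photons per
exposure); graded partial restriction and higher-order n-body enhancement
are deliberately excluded so that every flag can be checked against an
exhaustive pairwise oracle. The window comparison carries a 1e-9 relative
guard so distances constructed to sit exactly on a boundary are inside.
An optional mode draws each labeled antibody's dye count from
Poisson(1.35), the measured mean dye-to-antibody ratio, with all dyes
co-located (co-located dyes sit at distance 0, below `d_min`, and never
gate each other). The conventional rule makes every labeled fluorophore
emissive regardless of geometry.

Rendering bins emitters into half-open pixel bins (row and column indices
both increase with the physical coordinate), convolves with a unit-mass
Gaussian PSF, adds a constant background, then optionally applies Poisson
shot noise and zero-mean Gaussian read noise clipped at zero. Optics
defaults — 325 nm pixels (a 6.5 µm camera pixel behind a 20× objective),
PSF sigma 170 nm (green emission at moderate NA), background 10
photons/px, read noise 3 photons — are documented assumptions, not
measured values. Because the PSF kernel is normalised, a centred
emitter's flux is conserved exactly; the test suite checks 0.5%.

## Quantification chain

**Segmentation** is a classical edge-detection pipeline: Gaussian
smoothing (`smooth_sigma` = 3 px), Sobel gradient magnitude (kernels
`1/8·[[-1,0,1],[-2,0,2],[-1,0,1]]` and its transpose; the stencil is
undefined on the frame border, which is therefore zeroed), Otsu (or
fixed) threshold on the gradient map, morphological closing (disc radius
3), hole filling, and removal of components below `min_object_area`.
The thresholded gradient forms a band straddling the true boundary, so
the filled mask reaches the band's *outer* edge; a final erosion of
`ceiling(smooth_sigma) + 1` px recenters the mask on the boundary. The
smoothing default is deliberately generous: it suppresses intracellular
cluster texture so the gradient map is dominated by the cell outline and
the mask does not adapt to how clustered the staining looks — on a
count-conserving control channel, a texture-adaptive mask would
manufacture spurious dose trends. On a noiseless disk (foreground 100,
background 10) the pipeline's intersection-over-union with the true disk
is 0.91. A constant image returns an empty mask with a warning; empty
masks are hard errors at quantification, so a failed well is loud but
does not kill a plate.

**Masked mean intensity** is the summed intensity over the mask divided by
the masked pixel count. **SNR** is defined here as
(mean(foreground) − mean(background)) / sd(background), with the
background taken outside the mask dilated by 5 px to exclude the PSF
halo. This definition is the package's own documented choice; SNR
comparisons are therefore internally consistent, and no attempt is made
to reproduce any particular instrument's printed SNR values.

**Colocalization** is the standard Pearson coefficient over masked pixel
pairs, with a whole-frame option, plus a joint 2D intensity histogram
(64 equal-width bins per channel spanning the masked min–max; half-open
bins, last bin closed).

**Dose–response.** Within each (dye, time) stratum every well is divided
by the mean of that stratum's untreated wells, so controls sit at exactly
1. Conditions are compared against their stratum controls with a
two-sided Welch t-test, starred `*` below 0.05 and `**` below 0.01, with
no multiple-testing correction (stars annotate conditions individually;
the table metadata says so). The per-time-point normalization denominator
and the choice of Welch's test are this package's documented choices.
Onset concentrations of an increasing response are found by hinge
regression — flat baseline, then a linear rise in log-concentration, with
every tested concentration (except the last two) as a candidate
breakpoint — and declared detected only when the rise slope exceeds twice
its standard error. Hill-curve fits use Levenberg–Marquardt least squares
with data-driven starting values.

## The simulated plate experiment

`run_experiment()` composes everything: per exposure time, replicate and
cell, it draws a footprint and receptor field, applies disruption at each
dose, emits and renders both channels, segments the cell on the
*conventional* channel (which is blind to clustering, so the mask cannot
depend on the treatment effect), and quantifies both channels under that
mask. Wells pool their `n_cells` cells area-weighted. Every random stage
draws from a seed obtained by hashing the master seed with a
human-readable stage label, so any single well can be re-simulated in
isolation and a rerun is byte-identical.

One design choice deserves emphasis: within a replicate, the footprint,
field, labeling and the per-receptor disruption uniforms are drawn from
streams that do *not* include the dose. The dose series of a replicate
therefore "treats" the same virtual cells, and because the relocation
uniforms are drawn before any destination, the set of relocated receptors
is nested as dose increases. This common-random-numbers coupling removes
between-cell noise from within-replicate dose contrasts — the monotone
dose trend of the proximity channel is visible already at triplicate
scale — while replicates remain fully independent, so replicate standard
deviations and t-tests retain their usual meaning.

Default problem sizes, chosen once as the study conditions: dose grid
{0, 0.01, 0.1, 1, 10, 100} µg/mL (serial dilution), times {2, 8, 24} h,
triplicate wells, 6 cells per well, 64×64 px frames. A full grid is 108
wells (648 cell renderings per channel) and runs in roughly a minute and
a half on one core.

## What the synthetic data can and cannot show

The generator reproduces the qualitative structure of the real assay:
clustered vs dispersed membranes separate cleanly in AIE intensity and
SNR; the two channels rendered from the same labeled receptor set
correlate strongly (Pearson ≈ 0.85 under the default optics); the
conventional channel stays within its replicate noise of 1.0 across all
doses and times while the AIE channel falls monotonically with dose at
24 h, with fewer doses reaching significance at 2 h than at 24 h.

It does not emulate several features of real data: cell-to-cell
expression heterogeneity beyond Poisson statistics, membrane topography
and 3D geometry, receptor diffusion and internalization, photobleaching,
spectral bleed-through, or instrument-specific camera calibration.
Passing tests on synthetic data validate the analysis chain and the
internal consistency of the forward model — they do not certify any
particular instrument's absolute numbers, and printed values from real
imaging systems (SNRs, correlation coefficients) are treated as
qualitative ordering targets only.

Two quantitative caveats surfaced by the package's own tests are worth
recording. First, segmentation-derived masks sit a few pixels inside the
true cell outline, and cluster offspring are slightly interior-biased
(offspring beyond the footprint are discarded), so at saturating
disruption the conventional channel drifts about 2–4% below 1.0 — within
replicate noise at the default study size, but a real bias of the
mask-based readout. Second, the masked mean intensity is not linear in
the disrupted fraction: relocating a receptor both removes it from its
cluster *and* thins the cluster's local density, so the AIE signal falls
roughly quadratically in the disrupted fraction at the default cluster
density. A Hill curve fitted to the normalized intensity consequently
*underestimates* the disruption model's EC50 by roughly a factor of two
(fitted ≈ 0.55–0.6 µg/mL against a generative 1 µg/mL). This is a
genuine property of proximity-gated readouts, not a fitting artifact:
the apparent potency of a cluster-disrupting drug measured through an
AIE intensity curve is higher than its occupancy EC50. Analyses that
need the mechanistic EC50 should fit the disrupted fraction (or a
quadratic-response model), not the raw intensity.

## Numerical and degenerate-input policy

- All window and interval comparisons are closed; the AIE window uses a
  1e-9 relative tolerance at its edges.
- Rejection sampling is used for uniform points in a footprint; hard-core
  thinning is greedy in generation order (clusters first, then the
  dispersed pool).
- A constant image segments to an empty mask with a warning; quantifying
  an empty mask, a constant channel, a zero-spread background, or an
  out-of-bounds emitter is an error naming the offending object.
- TIFF output stores values scaled by a recorded power of two (the
  writer's 32-bit path passes through single precision; round trips agree
  to about 1e-7 relative). Pixel size and scale live in a JSON sidecar.
- Fields serialize to CSV with 17 significant digits, making receptor
  round trips lossless; experiment tables use fixed 15-digit formatting so
  reruns are byte-identical.
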