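---
title: "Depth sensing in spatially-offset Raman spectroscopy: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Depth sensing in spatially-offset Raman spectroscopy: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sorsdepth)
```

## The problem

Spatially-offset Raman spectroscopy (SORS) separates the excitation line
from the detection line by a lateral offset $\Delta s$. Photons detected
at larger offsets have, on average, dived deeper through the turbid
medium before re-emerging, so increasing $\Delta s$ biases the measured
Raman signal toward subsurface layers. For a bilayer sample — a finite
top layer of thickness $t$ with absorption $\mu_a$ and reduced
scattering $\mu_s'$ over a semi-infinite bottom layer of a different
Raman-active material — the practical question is: *which offset probes
which depth?*

`sorsdepth` answers it with a similarity-crossover construction. Every
preprocessed spectrum $\vec S$ is compared with the two pure-material
signatures $\vec R$ through the spectral angle mapper (SAM),

$$\mathrm{SAM}(\vec R,\vec S)=
  \frac{\sum_i R_i S_i}{\sqrt{\sum_i R_i^2}\sqrt{\sum_i S_i^2}},$$

the cosine of the angle between the spectra across wavenumber channels
(+1 identical direction, 0 orthogonal). As $\Delta s$ grows,
SAM against the top material falls while SAM against the bottom material
rises; the offset where the two curves intersect, $\Delta s_{CO}$, is
the offset at which both layers contribute about equally, and is
interpreted as the offset probing the interlayer depth $t$. Collecting
$(\Delta s_{CO}, t)$ pairs over phantoms of varying thickness, one
power-law depth model is fitted per optical-property recipe:

$$t^* = A\,\Delta s_{CO}^{\,\varphi},$$

with $t^*$ in micrometres and $\Delta s_{CO}$ in millimetres, so $A$
carries units $\mu m\,mm^{-\varphi}$. The forward and inverse forms
(`predict_depth()`, `required_offset()`) then convert between target
depth and required offset for samples with known optics.

## The synthetic-data generator

No public SORS cube repositories exist for this design, so the package
ships a first-class simulator with known ground truth.

**Photon transport.** `sample_photon_paths()` launches photons straight
down at the origin and walks them isotropically: step optical depths are
exponential with unit mean, converted to length with the local
$\mu_s'$; absorption attenuates the photon weight continuously by
$e^{-\mu_a \ell}$ along each segment. The walk uses the reduced
scattering coefficient in an isotropic (similarity-transformed) walk
rather than an anisotropic phase function, because the phantoms are
characterized by $\mu_s'$ alone. The bottom layer is semi-infinite with
configurable properties (defaults $\mu_a = 0.1$, $\mu_s' = 5$ cm$^{-1}$,
a polyamide-like choice). A photon is detected when it re-crosses the
surface; its lateral exit distance along the scan axis is folded by
symmetry and binned on the offset grid (0.25 mm bins by default). One
Raman conversion site per detected photon is drawn uniformly over its
scattering events by reservoir sampling; the per-bin
`fraction_bottom` is the detected weight with conversion site below the
interface divided by all detected weight.

Two deliberate simplifications deserve attention. First, drawing the
conversion site uniformly over *scattering events* weights a layer by
its event density ($\propto \mu_s'$): when the two layers differ
strongly in scattering (for example a lipid-emulsion top at
$\mu_s' = 200$ cm$^{-1}$ over muscle-like material at 5 cm$^{-1}$), the
top layer is over-represented relative to a per-pathlength Raman model.
The crossover construction is self-consistent under this convention —
the ground truth the tests compare against is the fraction table of the
same transport model — but absolute crossover offsets for strongly
mismatched layers should not be read as quantitative tissue
predictions. Second, photons are terminated by Russian roulette below
weight $10^{-4}$ (survival 0.1), which keeps the estimator unbiased
while bounding run time.

**Cube synthesis.** `simulate_cube()` realizes the linear-mixture
hypothesis: at offset $i$, each line-position spectrum is
$w_i\,[f_i S_{bottom} + (1-f_i) S_{top}]\times\text{exposure}$ plus a
broad Gaussian fluorescence baseline per material (the phantoms'
endogenous fluorescence has no published shape; a single broad band per
material is the simplest credible choice). Artifacts are then injected
in physical order: spectrometer smile (a polynomial channel shift
across spatial rows, quadratic by default), Poisson shot noise on
counts, Gaussian read noise, and Poisson-counted single-channel cosmic
spikes with uniform amplitude. Reference signatures are Gaussian band
sums (`make_reference_spectrum()`); the built-in pair
(`default_reference_library()`) is patterned on a silicone elastomer
and a polyamide, with band widths automatically widened when the axis
is sampled more coarsely than the instrument-scale ~1.9 cm$^{-1}$ per
channel so that bands always span several channels. The two raw
signatures are scaled to equal population standard deviation; after SNV
both references have identical norm, which places the SAM crossover of
a noise-free mixture exactly at mixing fraction 1/2 — this is what
makes the fraction-table crossing a valid ground truth for the
pipeline's crossover.

**Determinism.** All randomness derives from one root seed;
per-stage streams (photon walk, shot, read, cosmic) use fixed seed
offsets, so identical configuration and seed reproduce cubes
bit-for-bit while individual stages remain independently reproducible.

**What the simulator does not emulate.** Anisotropic scattering phase
functions, wavelength-dependent optics, detector nonlinearity and
saturation, dark current drift, spatial inhomogeneity of the layers,
and the spectral complexity of real tissue. Passing the recovery tests
therefore demonstrates the *analysis chain* is correct under the stated
forward model, not that the forward model captures every property of
real measurements.

## Preprocessing chain

`preprocess_cube()` applies, in order: channel truncation, cosmic ray
removal, smile correction, wavenumber calibration, system-response
correction, bubble baseline removal, SNV. The order follows standard
practice for line-scanning Raman imagers.

- **Truncation** removes the leading `n_drop` channels (default 120 of
  1024, leaving 904) that sit below the long-pass filter cutoff.
- **Cosmic rays** are detected per spectrum from the residual against a
  running median (window 5): a channel is replaced when the modified
  z-score (median/MAD) of that residual exceeds 8 *and* the residual
  exceeds 0.2 of the local median level. The running median
  annihilates only features narrower than half its window, so smooth
  Raman bands (always several channels wide at this sampling) leave
  near-zero residual and are never touched, while one- or two-channel
  spikes stand out fully; the relative-prominence guard keeps band
  apexes safe even in noise-free spectra where the MAD is degenerate.
  Flagged channels are replaced by linear interpolation of untouched
  neighbors.
- **Smile** is estimated from a calibration frame holding one strong
  band: per-row intensity centroids are referenced to row 1 and
  smoothed by a quadratic fit in row index (CCD smile is a low-order
  curvature); correction resamples each row by its negative shift with
  linear interpolation, extending edges by nearest value.
- **Wavenumber calibration** detects band centroids of the standard
  frame, pairs them in order with the known band list (a conventional
  acetaminophen-type list ships as a config default), and fits a cubic
  (configurable) pixel-to-cm$^{-1}$ polynomial; a non-monotonic axis is
  an error, not a warning.
- **System response** divides by the row-averaged measured response of
  a certified relative-intensity standard and multiplies by the
  certified curve, normalized to unit mean gain. Certified values are
  config inputs, never hard-coded.
- **Baseline** uses a bubble construction: the largest circle that
  slides up under the spectrum between successive contact points is
  inserted recursively, splitting at each new interior contact, until
  intervals are narrower than `min_bubble_width` (default 75 channels,
  wider than any Raman band yet well below fluorescence curvature);
  such finished intervals are completed with the chord between their
  contact points (the limiting maximal bubble). The spectrum is
  de-tilted by its endpoint chord first and the intensity axis is
  rescaled to channel units so circle geometry is meaningful; spectrum
  edges start "uncontacted" and intervals holding one use edge-aligned
  half bubbles so the baseline can rise at the ends. By construction
  the baseline never exceeds the spectrum and the recovered Raman
  signal is non-negative.
- **SNV** subtracts the mean and divides by the population standard
  deviation (the chemometrics convention); constant spectra are an
  error for the exported function, while inside `preprocess_cube()`
  all-zero spectra from empty offset bins are left at zero and counted
  in the metadata, so a cube with signal-starved far offsets still
  processes.

## SAM curves, crossover, and detectability

`sam_curve()` computes the SAM of every line-position spectrum against
both references and averages the per-spectrum values at each offset
(mean-of-SAM; SAM-of-mean-spectrum is available behind a flag — with 42
homogeneous positions the two differ negligibly, but mean-of-SAM
degrades more gracefully when single rows are corrupted). For
SNV-normalized inputs SAM equals the Pearson correlation, a useful
cross-check asserted in the tests.

`find_crossover()` works on $D(\Delta s) = \mathrm{SAM}_{top} -
\mathrm{SAM}_{bottom}$: the first sign change from positive to
non-positive is located and $\Delta s_{CO}$ interpolated linearly
inside the bracket (the 0.25 mm grid is fine relative to the curves'
curvature, so linear interpolation suffices). If $D \le 0$ already at
the first grid point the crossover lies before the grid
(`below_grid`); with no sign change the status is `none_detected`.
When the detected light has degenerated to noise, SAM values scatter
around zero at a scale of about $1/\sqrt{N}$ ($\approx 0.03$ at 904
channels) and $D$ can cross zero spuriously; a crossing is therefore
accepted only while $\mathrm{SAM}_{total}$ at the bracket exceeds a
floor of 0.2 — several noise standard deviations up, far below the
$\gtrsim 1$ values of genuine crossovers. This implements
quantitatively the observation that for strongly scattering top layers
the signal transitions from the top material to stochastic noise and
the crossover loses its physical meaning. Rejected noise crossings are
counted in the result.

`find_detectability_limit()` reports the offset where the
bottom-material SAM, smoothed by a centered moving average (window 5),
peaks — provided the maximum is interior and the subsequent decrease
exceeds twice the MAD of the curve's increments, a guard that turns the
qualitative "plateau and turnover" rule into a testable criterion.

## Depth-model fitting

`fit_power_law()` fits $t = A\,\Delta s^{\varphi}$ by
Levenberg–Marquardt nonlinear least squares in the original space —
consistent with fitting the depth points directly rather than their
logs — initialized from the ordinary log-log regression; on noise-free
power-law data the two agree exactly, which the tests assert.
`build_depth_curves()` groups phantoms by identical optical properties,
uses only entries with a found crossover, and refuses to fit groups
with fewer than two usable points, reporting them as unfittable instead
— with strongly scattering top layers the crossover is not physically
meaningful, and forcing a curve through such data would manufacture
parameters. No uncertainty intervals beyond the residual norm are
reported.

## Study orchestration and problem sizes

`run_phantom_study()` drives the full loop — transport, synthesis,
preprocessing, SAM, crossover, plateau, per-recipe fits — over a
phantom table (the shipped table holds 10 recipes spanning
$\mu_a = 0.09$–$8.15$ cm$^{-1}$ and $\mu_s' = 0.02$–$78$ cm$^{-1}$ with
six thicknesses each, 60 phantoms). Two profiles are provided:
`"full"` mirrors the instrument geometry (40 offsets $\times$ 42 line
positions $\times$ 1024 channels, $10^5$ photons per phantom), while
`"micro"` keeps the full 40-offset grid and the complete processing
chain on reduced sampling (4 line positions, 192 channels, 1500
photons) — the profile used throughout the test suite, chosen so a
60-phantom study is a routine interactive run while still exercising
every stage. The end-to-end recovery checks use an intermediate
geometry (40 offsets, 6 line positions, 256 channels, $10^5$ photons)
where Monte Carlo error in the ground-truth fraction tables is small
against the 0.25 mm grid. Reports carry the seed and a configuration
hash; rerunning with the same seed reproduces them exactly.

## Decided questions

- The acquisition grid is stated in places as covering 0–10 mm, but 40
  measurements at 0.25 mm from 0 mm end at 9.75 mm; the package uses
  the 40-offset grid and documents the rounding.
- Reference spectra are preprocessed exactly like measurements
  (baseline-removed, SNV) before entering SAM; normalizing only one
  side would make the crossover depend on raw intensity scales.
- The printed preprocessing order is followed literally; in particular
  baseline removal precedes SNV and follows the response correction.
- $A$ is treated as carrying $\mu m\,mm^{-\varphi}$, matching
  thickness tables in micrometres and offsets in millimetres.

## Known limitations

The transport model's event-density conversion bias (above) matters for
strongly scattering-mismatched bilayers; the isotropic walk ignores
anisotropy beyond the similarity relation; the fluorescence model is a
single broad band per material; bubble baselines leak a few percent of
the baseline amplitude under dense band clusters, which propagates as a
1–2% RMS effect through SNV; and SAM is a two-endmember method — more
than two materials require unmixing approaches out of scope here.
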