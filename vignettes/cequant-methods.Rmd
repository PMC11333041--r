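---
title: "Quantifying a single synaptic contact: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying a single synaptic contact: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Club endings (CEs) are large auditory afferent terminals that each form a
single, identifiable mixed electrical/chemical synaptic contact on the
lateral dendrite of the zebrafish Mauthner cell. Protein-retention expansion
microscopy enlarges these contacts roughly 3.9-fold linearly, so that the
internal organization of the contact — dozens of gap-junction (GJ) plaques,
an interleaved adherens-junction (AJ) mesh, and small peripheral glutamate
receptor (GluR2) patches — becomes resolvable on a confocal microscope.

`cequant` implements the measurements this kind of experiment needs:

* contact morphometry (oval outline fit, long/short diameters, area,
  short/long ratio) and expansion-factor / isotropy statistics;
* GJ punctum segmentation, per-punctum area, Sturges-rule histograms, and
  connexon-number estimates;
* thresholded Manders colocalization between marker channels;
* a center/periphery partition of the contact with corrected total
  fluorescence (CTCF) comparisons;
* labeling occupancy (the fraction of the contact surface covered by each
  marker);
* two-channel line scans with subpixel peak fitting for pre/postsynaptic
  offset measurement.

Because raw image data for such experiments is rarely shareable, the package
also contains a synthetic scene generator that produces calibrated image
stacks from a known ground truth. Every measurement stage is validated
against that ground truth in the test suite, and the `analysis/` scripts
run the full study on synthetic data.

## The synthetic contact model

A scene is generated in pre-expansion (biological) coordinates and carried
through an explicit expansion transform and imaging model.

**Contact geometry.** The contact is an oval on a shallow paraboloid cap
(`z = c * rho^2`, with `rho` the elliptical radial coordinate; concavity
`c = 1 um` post-expansion by default, `c = 0` gives a flat contact). The
long diameter is drawn from Normal(2.11, 0.228) um and the short/long ratio
from Normal(0.77, 0.111), truncated to [0.40, 0.98] — the published
morphometry of non-expanded CE contacts (group means with SDs back-computed
from the reported SEMs and group sizes).

**Gap-junction puncta.** The per-contact punctum count is
round(Normal(36.73, 4.27)), truncated at 5; the SD is back-computed from
the reported SEM (1.287, n = 11). Per-punctum post-expansion areas follow a
log-normal clipped to the observed range [0.06, 1.99] um². Its `sdlog`
(0.68) makes the central 99% of mass span that range; its `meanlog`
(-1.204) is calibrated so the mean punctum area (0.378 um² image scale)
reproduces the reported per-contact total of ~12,400 connexons at 12,000
connexons/um² and a 13.4x areal factor. Puncta are placed by largest-first
rejection sampling with a minimum edge-to-edge gap (0.15 um post-expansion),
fully inside the contact and pairwise disjoint.

Two feasibility mechanisms keep dense draws physical. First, the contact
geometry is redrawn while the total effective punctum area exceeds 52% of
the contact area — a contact cannot hold more disjoint plaque area than
that, and the published per-contact totals imply ~40% packing. (This
slightly right-shifts the accepted contact-size distribution; counts and
punctum-area marginals are untouched.) Second, a placement relaxation
ladder drops the receptor-avoidance constraint, then the inter-punctum gap,
and finally shrinks a stuck punctum by 10% (at most five times) rather than
aborting; disjointness is never relaxed.

**Receptor patches and the unlabeled fraction.** GluR2 patches (12–18 per
contact, radius 0.3–0.55 um post-expansion) have their centroids confined
to the peripheral annulus whose area is one quarter of the contact — the
published location of the glutamatergic zone. The unlabeled fraction of the
contact is modelled as 3–5 dark membrane patches (radius 0.3–0.5 um) that
punctum placement treats as obstacles. An alternative sub-resolution
"guard ring" around each punctum is available (`guard_band_post`) but
defaults to 0: a margin much narrower than the PSF cannot be recovered by
any intensity measurement, so modelling the unlabeled area as resolvable
patches keeps the generator's ground truth measurable — the noiseless
occupancy-recovery test then checks the measurement rather than the optics.
The AJ mesh is everything inside the contact not claimed by a punctum,
receptor patch or dark patch, which produces the observed interleaved,
engulfing pattern and makes the four ground-truth occupancy fractions sum
to exactly 1.

With these defaults the mean ground-truth occupancies are roughly GJ 31%,
AJ 51%, GluR2 13%, unlabeled 5%. The published percentages (38/35/19/8)
guided this calibration but are not reproduced exactly: in particular the
quarter-area annulus is only ~0.5 um wide after expansion, so it cannot
geometrically hold 19% of the contact as small disjoint patches. The
qualitative ordering AJ ~ GJ >> GluR2 > unlabeled is preserved and tested.

**Expansion transform.** Linear factor `k` (default 3.9) along the long
axis and `k * r` along the short axis (`r` = 1 by default; `r = 0.82`
reproduces the published S/L drop from 0.77 to 0.64 if one attributes it to
anisotropic expansion). With `r = 1`, areas scale by exactly `k²` and the
S/L ratio is invariant — both exact algebraic properties of the transform,
tested as such.

**Imaging model.** Each marker mask is rasterized at its surface height,
postsynaptic markers displaced along the local surface normal by their
offset (Cx34.1: 0.03 um; ZO1: 0.21 um; image scale, matching the published
peak-offset measurements on expanded tissue). The density is convolved with
an anisotropic Gaussian PSF — lateral FWHM 0.28 um, axial 0.49 um, the
midpoints of the stated instrument-resolution ranges — and intensities are
drawn as `Poisson(photon_scale * density + background) + N(0, read_noise)`,
clipped at zero. Defaults: 0.08 um/px, 0.4 um z-step, photon scale 500,
background 10, read noise SD 3 — a bright, well-sampled confocal
acquisition. Line-scan scenes use a dedicated flat side-view renderer (the
membrane seen edge-on) because that is the geometry in which peri-plaque
offsets are measurable.

## Measurement methods and numerical choices

**Contact outline.** Threshold (Otsu by default), morphological closing
with a 0.6 um brush (bridging the gaps between neighbouring puncta so a
punctate connexin channel yields a single contact component; the image is
padded by the brush radius first so the border never distorts the closing),
largest connected component, hole filling, then a second-moment ellipse
fit: diameters are `4 * sqrt(eigenvalue)` of the pixel covariance — the
axes of the ellipse with the same second moments as the mask. This is
reproducible on concave outlines where caliper diameters are not. Area is
the mask pixel count times the pixel area. All outputs are in micrometres;
nothing pixel-valued is stored.

**Projections.** Both maximum and sum projections are provided. The default
analysis recipe segments puncta on the *sum* projection: with a 0.4 um
z-step and 0.21 um axial PSF sigma, a structure's peak intensity in a max
projection depends on where its surface lies relative to the slice grid
(up to ~40% attenuation), which silently drops the faintest small puncta;
the summed intensity is invariant to it.

**Punctum segmentation.** In-ROI Otsu threshold, connected components,
minimum-area filter at 0.05 um² (just below the smallest plaque the method
should report). `segment_puncta()` leaves watershed splitting off, but the
pipeline default enables distance-map watershed: on ground-truth scenes it
splits blur-bridged neighbours without ever over-splitting, reducing the
count bias from about -2.7 to about -1 per ~37 puncta. Connexon numbers are
`area / areal_expansion_factor * 12000`, rounded per punctum; histogram bin
counts follow Sturges' rule, `k = ceiling(1 + log2(n))`.

**Manders coefficients.** Thresholded Manders: `M1` is the fraction of
above-threshold channel-A intensity in pixels where B is above its own
threshold, and symmetrically for `M2`. Thresholds are independent per
channel (Otsu within the ROI by default; manual and Costes-regression
alternatives provided). A zero denominator yields an explicit undefined
flag, never a silent zero, and batch means exclude such contacts with a
warning.

**Center/periphery and CTCF.** The center ROI is the similar ellipse with
both semi-axes scaled by sqrt(3/4) — exactly three quarters of the contact
area in the continuum, within one boundary-pixel band on the raster; the
periphery is the set difference, so the two ROIs partition the contact
pixel-exactly. CTCF is `integrated density - area x background mean`
(negative values reported and flagged). Normalized comparisons divide CTCF
by ROI area and then by the largest channel x ROI value of that contact;
normalizing per-ROI instead would force every ROI's larger channel to 1,
which is inconsistent with published example values.

**Occupancy.** Per channel, the above-threshold fraction of the ROI. With
exclusive assignment (default), a pixel above several thresholds counts
only for the channel with the largest threshold-normalized intensity, so
channel fractions plus the unlabeled fraction sum to exactly 1; the
non-exclusive mode double-counts overlap, and both are exposed because
either convention appears in practice.

**Line scans.** Bilinear interpolation at half-pixel steps along the
segment, averaged over a perpendicular band. Peaks are localized by a
Gaussian fit (Levenberg–Marquardt) within ±0.3 um of the discrete maximum,
falling back to three-point parabolic interpolation if the fit fails;
boundary maxima are flagged and excluded from statistics. Offsets are
signed along the line (B minus A); group statistics use magnitudes, with
one-way ANOVA and Tukey HSD across conditions. Peak localization, not
resolution, limits the measurement: a 0.03 um offset — an order of
magnitude below the PSF FWHM — is recovered without bias in the noiseless
limit, and with ~0.004 um SD at default noise.

## What the synthetic data does and does not show

The generator reproduces the geometry, layout statistics, PSF and noise of
the study conditions, so passing tests demonstrate that the measurement
code recovers known answers under realistic blur and shot noise — counts to
within ~1 punctum in ~37, areas to ~4% median error, occupancies to 0.03,
offsets to a few nanometres. It does not emulate antibody labeling
stochasticity, fluorophore "spatial amplification" beyond Gaussian blur,
gel-mechanics distortion beyond the global anisotropy knob, tissue
autofluorescence, or chromatic aberration (ruled out experimentally in the
source study by swapping secondary antibodies — the same control the
line-scan module implements). Published Manders values and occupancy
percentages from real tissue are therefore calibration context for the
generator, not quantities the package claims to predict.

## Problem sizes

The bundled analyses use 50 synthetic contacts for puncta statistics, 8 for
colocalization and occupancy, 20 for isotropy, and 30–39 line-scan profiles
per offset condition — comparable to the published group sizes (11 contacts
for puncta, 30–39 profiles per offset group) while keeping a full run in a
few minutes on one core.

## Known limitations

* The contact-outline fit underestimates the diameters by ~5–10% on
  punctate channels, because the outermost AJ rim carries no connexin
  signal; fitting the summed multi-channel image avoids this where the
  extra channels exist.
* Blur-bridged puncta closer than about two PSF sigmas remain a single
  component even with watershed splitting; the residual count bias is about
  -1 per contact at defaults (the source study notes the same limitation).
* The Costes threshold search uses the standardized principal-axis
  regression and a downward scan over observed intensities; it is provided
  as an alternative, not the default, and is only lightly validated.
* `r != 1` turns circular puncta into ellipses; their disjointness is then
  checked in the pre-expansion frame only.
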