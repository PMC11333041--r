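# cequant

Quantification of single synaptic contacts in expansion microscopy.

Zebrafish club endings (CEs) are large auditory afferent terminals, each
forming one identifiable mixed electrical/chemical synaptic contact on the
Mauthner-cell lateral dendrite. After ~3.9x protein-retention expansion,
confocal imaging resolves the interior of a single contact: several dozen
gap-junction (GJ) plaques of widely variable size, an interleaved
adherens-junction (AJ) mesh, and small peripheral glutamate-receptor
(GluR2) patches. `cequant` is an R package plus a set of analysis scripts
that turn such multi-channel stacks into numbers:

* **Morphometry** — oval contact fit (second-moment ellipse: long/short
  diameters L, S; area A; ratio S/L), expansion factors
  (linear = L̄_exp / L̄_non, areal = Ā_exp / Ā_non), and S/L isotropy
  statistics (Student's t, per-group normal fits).
* **Puncta** — GJ segmentation inside the contact ROI, per-punctum area,
  Sturges-rule histograms (k = ⌈1 + log₂ n⌉), and connexon estimates
  (area / areal factor x 12,000 connexons/µm²).
* **Colocalization** — thresholded Manders coefficients
  M1 = Σ A′ᵢ[B′ᵢ > 0] / Σ A′ᵢ (and symmetrically M2), with independent
  per-channel thresholds (Otsu / manual / Costes).
* **Center/periphery** — central ellipse at √0.75-scaled axes (¾ of the
  area) vs the remaining annulus; CTCF = integrated density − area x
  background mean; normalized fluorescence-per-area comparisons.
* **Occupancy** — per-channel labeled-area fractions of the contact, with
  exclusive pixel assignment so fractions + unlabeled sum to 1.
* **Line scans** — two-channel profiles with subpixel Gaussian peak
  fitting; signed pre/postsynaptic peak offsets; ANOVA + Tukey across
  conditions (including the fluorophore-swap control).

No raw microscopy data is required: a synthetic scene generator renders
ground-truth contacts (calibrated geometry and marker layout, Gaussian PSF,
Poisson + read noise) so every stage is validated against known answers.
See `vignettes/cequant-methods.Rmd` for the model and all parameter
calibrations.

## Worked example

Generate one expanded contact, segment its gap junctions and estimate
connexon numbers:

```r
library(cequant)

set.seed(42)
scene <- apply_expansion(sample_contact())       # ground-truth geometry
stack <- render(scene, imaging_model(), channels = "Cx35.5")

img <- sum_project(stack)$channels[["Cx35.5"]]
fit <- fit_contact_outline(img, stack$pixel_size_xy)
lab <- segment_puncta(img, fit$mask, stack$pixel_size_xy, split_touching = TRUE)
rec <- measure_puncta(lab, stack$pixel_size_xy, areal_expansion_factor = 13.4)
sm  <- contact_summary(rec)

sm$n                      # detected puncta  -> 42 (ground truth: 43)
round(range(rec$area_um2), 2)   # punctum areas   -> 0.08 1.29 um^2
sm$total_connexons        # connexons/contact -> 15034
```

The numbers mean: this synthetic contact carries 43 gap-junction plaques
(42 recovered by the default segmentation), with image-scale areas from
0.08 to 1.29 µm²; dividing by the 13.4x areal expansion factor and
multiplying by the crystalline packing density of 12,000 connexons/µm²
estimates ~15,000 intercellular channels for the whole contact.

The full study lives in `analysis/01_simulate.R` … `06_linescan.R`; each
script prints what it found and writes its tables under `results/`. For
example `analysis/06_linescan.R` prints:

```
cx_cx           |d| = 0.031 +- 0.0007 um (n = 37)
cx_zo1          |d| = 0.211 +- 0.0010 um (n = 30)
cx_zo1_swapped  |d| = 0.209 +- 0.0006 um (n = 39)
one-way ANOVA: F = 18500.0, p = 2.17e-132
```

i.e. the pre- and postsynaptic connexin peaks are essentially aligned
(~0.03 µm), the scaffold protein ZO1 sits ~0.21 µm behind the presynaptic
connexin, and the offset survives swapping the fluorophores, so it is not
chromatic aberration.

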