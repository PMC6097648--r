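---
title: "Quantifying gap-junction plaques, active zones and dye coupling in confocal stacks"
author: "jonquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying gap-junction plaques, active zones and dye coupling in confocal stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jonquant)
```

# The scientific problem

In the *Drosophila* escape circuit, sound-sensitive Johnston's Organ
neurons (JONs) of the antenna synapse onto the giant fiber (GF)
interneuron through mixed electrical/chemical synapses.  Three
fluorescence readouts quantify this connectivity in 8-bit confocal
stacks acquired at 0.22 µm in-plane pixels:

* **Dye coupling** — Neurobiotin (NB) injected into the GF crosses gap
  junctions retrogradely into coupled JON axons; the mean NB
  cross-sectional area near the anterior tip of the GF dendrite
  measures how many axons are coupled.
* **Putative active zones (AZ)** — a Brp-short fluorescent fusion
  marks presynaptic active zones; the overlap volume of the binarized
  Brp and GF-dendrite (dextran) channels estimates chemical synaptic
  contact onto the GF.
* **Gap-junction plaques** — anti-ShakB immunostaining labels innexin
  plaques of roughly 1 µm diameter; their volume per JON territory
  (JO-A lateral, JO-B medial), and the fraction colocalized with Brp,
  characterize where junctions form.

`jonquant` implements the complete measurement chain for these
readouts, plus a synthetic phantom generator with ground truth so that
every stage — and the group statistics built on it — can be validated
without access to raw microscopy data.

# Pipeline stages

## Artifact removal by grayscale top-hat

Brp-short overexpression produces large, non-specific agglomerations
that do not represent active zones.  `removeAgglomerations()` removes
them with a white top-hat: a per-slice disc **minimum filter (radius 3
px)** followed by a **maximum filter (radius 3 px)** — a grayscale
opening — subtracted from the original with 8-bit saturating
arithmetic.  Structures strictly smaller than the disc survive at full
value; anything wider than the disc cancels.  Two conventions are
pinned for determinism:

* the disc of radius $r$ contains every pixel whose centre distance is
  $\le r$; radius 1 is the full 3×3 square, so that the 1-pixel
  outline (below) is the classic 8-connected shell;
* filters operate per-slice (2D), matching how stack rank filters are
  conventionally applied; a 3D variant is deliberately not offered.

A linear min–max contrast rescale follows by default
(`rescale = TRUE`).  Because histogram-shape thresholds are *not*
invariant to rescaling, the step is an explicit, logged flag and the
test suite exercises both settings.  The "3 pixels" parameter is
interpreted as a radius (the convention of the common rank-filter
implementations); this choice is fixed in `pipelineConfig()` rather
than guessed silently per run.

## Pooled stack-histogram auto-thresholding

Each channel is binarized at a level chosen from one pooled 256-bin
histogram of the whole stack (`stackHistogram()`), with bin 255
excluded ("ignore white") so saturated voxels never drive the level.
Foreground is intensity **strictly greater** than the level.  Three
methods cover the channel map used throughout
(`Brp → intermodes`, `GF/DA488 and NB → default`, `ShB → renyi`):

* **Intermodes** (`thresholdIntermodes()`): the histogram is smoothed
  repeatedly with a 3-bin running mean (mirror-reflected ends,
  iteration cap 10 000) until exactly two strict local maxima $j, k$
  survive; the level is $\lfloor (j+k)/2 \rfloor$.  A histogram that
  cannot be reduced to two modes is an error by contract — the method
  is only defined for bimodal input.
* **IsoData "default" variant** (`thresholdIsoData()`): bins 0 and 255
  are zeroed first (erased areas and saturation are not data), then
  starting from the midpoint of the nonzero support the level iterates
  $t \leftarrow \lfloor(\mu_{\le t} + \mu_{>t})/2\rfloor$ to its fixed
  point.  The floor map is monotone, so the iteration terminates and
  cannot 2-cycle — this determinism is why floor, not round-to-nearest,
  is pinned.  A trimmed histogram whose mass sits in a single bin
  returns that bin.
* **Rényi entropy** (`thresholdRenyiEntropy()`): for orders
  $\alpha = \tfrac12, 1, 2$ the candidate level maximizes the summed
  background/foreground Rényi entropies over all splits of the nonzero
  support (argmax ties go to the lowest level).  The three sorted
  candidates $t_1 \le t_2 \le t_3$ are combined by the weighting rule
  of Sahoo, Wilkins and Yeager (1997): weights $(1,2,1)$ when both
  neighbouring gaps are $\le 5$ levels, $(0,1,3)$ when only the lower
  gap is, $(3,1,0)$ when only the upper gap is, $(1,2,1)$ otherwise,
  mixed through the cumulative probability mass between $t_1$ and
  $t_3$.  Each candidate is pinned to an exhaustive-split oracle in
  the tests.

## Derived measures

All measures consume binary masks and the voxel geometry
(`dx = dy = 0.22` µm, `dz` per manifest, anteroposterior slice axis,
and the sign that points medially):

* `perSliceArea()` — foreground area per slice; volume
  $= \sum \text{area} \times dz$.
* `overlapVolume()` — voxelwise AND volume: Brp ∧ GF is the putative
  AZ apposed to the dendrite; ShB ∧ Brp the plaque/AZ colocalization.
* `surfaceAreaProxy()` — the volume of the 1-pixel outline
  (mask AND NOT its radius-1 erosion, per slice) divided by the pixel
  size (0.22 µm); a one-pixel shell's volume over its thickness
  approximates the bounding surface.
* `partitionMedial()` — the mediolateral centre is the centroid of the
  largest 6-connected GF component (one global plane, not per-slice,
  so branches do not make the boundary wobble); the boundary lies
  `round(5/0.22) = 23` pixels medially; voxels strictly beyond are
  "medial", the boundary pixel itself is core.  The outputs are
  disjoint and exhaustive by construction.
* `nbCouplingArea()` — mean NB cross-sectional area over
  `round(10/dz)` slices centred on the anteriormost GF slice (the
  first slice with GF foreground; the window clamps at stack edges).
  Windowing is by physical length, so a non-1-µm `dz` is handled by
  the same rule.
* `colocalization()` — per region (JO-A / JO-B masks): ShB volume,
  ShB ∧ Brp volume, and percent colocalized
  ($100 \cdot \text{overlap}/\text{ShB}$; an empty region reports 0
  with a warning rather than failing a batch).

Sub-voxel tolerance (e.g. dilation before the AND) is deliberately not
applied: overlap is plain conjunction.

## Statistics

`anovaTukey()` runs per-group Shapiro–Wilk normality (reported, never
used to switch tests automatically), one-way ANOVA and Tukey–Kramer
HSD (valid under unequal group sizes), and reports group means ± SEM
with `N` = animals.  Star codes are `*` for $p \le 0.05$, `**` for
$p \le 0.01$, `***` for $p \le 0.001$, boundaries inclusive.
Shapiro–Wilk is the pinned normality test; general-purpose statistics
packages offer several and the choice is recorded here once.

# The phantom generator

`generatePhantom()` renders a parametric scene and passes it through a
simple optics/noise chain: separable Gaussian PSF (lateral
$\sigma = 0.08$ µm, axial $\sigma = 0.35$ µm by default — the regime
of a high-NA confocal at ~500 nm), Poisson shot noise (2 photons per
intensity unit), Gaussian read noise (sd 4), clipping and 8-bit
quantization at 0.22 µm pixels.  The scene comprises:

* a GF dendrite tube (radius 1.4 µm) swept along the AP axis with a
  gentle mediolateral bend, placed at 0.32 of the field width so the
  medial side has room for branches;
* straight medial branches (defaults 3–6.5 µm from the centreline,
  radius 0.5 µm) that exercise the 5 µm partition;
* ShakB plaques of 1 µm diameter, 24 in JO-A vs 6 in JO-B (the
  four-to-one control regime), with 22% / 17% of plaques carrying a
  colocalized Brp punctum;
* 150 scattered sub-micron Brp puncta and 25 AZ puncta placed on the
  dendrite surface;
* large agglomeration blobs (4 µm) present in the Brp-short channel
  and absent from the nc82-like channel;
* NB filling the dendrite plus a configurable number of coupled axons
  running anteroposteriorly on the lateral side.

Three non-obvious choices deserve their rationale:

* **Noise level.**  At punctate-structure SNR near 10 the Brp top-hat
  histogram degenerates to a single background peak with a smooth
  decaying tail, and Intermodes — whose contract requires a
  bimodalizable histogram — fails for a few percent of specimens.
  The defaults therefore sit at SNR ≈ 20, where the puncta form a
  distinct intensity mode and the failure rate was 0/100 phantoms.
  This is a property the method itself imposes on usable data.
* **Plaques stay off the dendrite.**  Plaques (and their colocalized
  Brp puncta) are rejected from a corridor around the dendrite and its
  branches.  This encodes the biological dissociation the pipeline
  must be able to detect: increasing gap-junction plaques raises ShB
  volume and ShB ∧ Brp colocalization but must not raise AZ-on-GF.
* **Bounded variability.**  `generateGroupStudy()` draws per-specimen
  lognormal multipliers (sdlog 0.15, truncated at ±2 sd) on four
  effect dimensions — JO-B plaque volume, coupled-axon count, medial
  branch length, AZ count — so that every realized scene is guaranteed
  to fit the field of view; the generator refuses out-of-bounds
  objects rather than clipping them silently.

`defaultGroupEffects()` provides four genotype-like presets: control;
an N+16-like group (JO-B plaque volume ×4, coupling ×1.8); an N-like
group (coupling ×0.15 — near-abolition, since multipliers must be
strictly positive); and an En-like positive control (AZ ×2.4, medial
branch length ×1.5, coupling ×1.7).

What the phantoms do **not** emulate: realistic axon morphology and
fasciculation, spatially varying background/autofluorescence, spectral
bleed-through, depth-dependent attenuation, or deformation between
specimens.  Passing recovery tests therefore demonstrates that the
measurement chain is correct and well-calibrated on data satisfying
its geometric assumptions — not that thresholds chosen on real tissue
are unbiased.

# Validation scales and reproducibility

The test suite validates each operation against independent
brute-force oracles (exhaustive rank-filter neighbourhoods, fixed-point
and exhaustive-split threshold oracles, counting oracles for every
volumetric measure) and then exercises the full chain at stack size
96×96×48 voxels: effect recovery over 20 seeded four-group studies
with n = 6 specimens per group, and null calibration over 20 seeded
exchangeable studies with n = 4.  These sizes were chosen as the
smallest at which all structures remain several voxels across and the
group tests are well powered; the generator's own default is
128×128×60.  One seed fixes a study completely: per-specimen child
seeds are derived arithmetically from the master seed.

`scripts/acceptance.R` regenerates a default four-group study
(n = 8, 128×128×60), runs the full pipeline and writes the derived
quantities (boundary conversion, JO-A/JO-B ratio, colocalization
percentages, recovered effect sizes and their Tukey p values) to JSON.

# Known limitations

* The 3D rotation of stacks to a standard anatomical position is a
  manual acquisition-side step; `jonquant` assumes pre-oriented input
  and records orientation as metadata (`apAxis`, `medialDirection`).
* Intermodes refuses histograms it cannot bimodalize; batch users
  should expect (and want) hard errors on degenerate channels rather
  than silent fallbacks.
* The surface-area proxy inherits the anisotropy of the outline
  definition (per-slice shells); it is a comparative measure, not an
  absolute surface estimate.
* Percent-colocalization denominators of zero return 0 with a warning,
  which slightly biases group means toward zero in near-empty regions.
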