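---
title: "Measuring peripapillary RNFL thickness from circle-scan OCT: models, phantoms, and design choices"
author: "rnflquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring peripapillary RNFL thickness from circle-scan OCT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnflquant)
```

## The measurement problem

The peripapillary retinal nerve fiber layer (RNFL) is the bundle of
ganglion-cell axons converging on the optic nerve head; its thickness,
measured on a circular OCT scan around the disc, is the standard structural
readout in glaucoma and neuro-ophthalmic disease. Built-in device
segmentation fails frequently in diseased eyes — epiretinal membranes,
posterior vitreous detachment, and low signal quality all derail the layer
tracer — and those failures propagate silently into the reported
thicknesses. This package implements the full alternative pipeline: denoise
the B-scan, segment the RNFL band with a U-Net, clean the predicted mask
morphologically, convert it to calibrated thickness, and report the seven
clinical values (global average plus six TSNIT sectors), with an evaluation
suite (Dice, sensitivity, specificity, MAE) around it.

Clinical circle scans are not shipped with the package. Instead, a
first-class synthetic phantom generator produces circle-scan B-scans with
*exact* ground truth, so that every stage — and the pipeline end-to-end — is
testable, seeded, and reproducible on any machine.

## The phantom model

A circumpapillary scan unrolls the circle into a rectangle: columns are
A-scans ordered Temporal–Superior–Nasal–Inferior–Temporal (TSNIT, A-scan 0
at the temporal meridian), rows are axial depth. The phantom's true
thickness profile is

\[
T(\theta) \;=\; b \;+\; u\,A\left[ G_{\sigma}(\theta - 67.5^\circ) +
G_{\sigma}(\theta - 292.5^\circ)\right] \;+\; J(\theta),
\]

where \(G_\sigma\) is a wrapped Gaussian (default \(\sigma = 27^\circ\))
centred on the superior-temporal and inferior-temporal sector centres —
the classic double-hump shape of a healthy TSNIT curve — \(u \sim
U(0.8, 1.2)\) is a per-phantom amplitude scale, and \(J \ge 0\) is smooth
jitter: five Gaussian bumps with uniform random centres, amplitudes
\(U(0, 16)\,\mu m\) and widths \(U(8^\circ, 20^\circ)\). Because \(u\) has
mean one and every jitter term is nonnegative, each profile value stays at
or above the baseline \(b\), and the expected circle average has the closed
form \(b + \bar h + n_J\,\bar a\,\bar s\sqrt{2\pi}/360\).

Group presets invert that expression: given a target circle-average
(controls 100.3 µm, non-arteritic anterior ischemic optic neuropathy 69.7
µm, optic neuritis 76.1 µm — the manually corrected group means the
phantoms are calibrated to), the baseline is solved so the Monte-Carlo mean
converges to the target. Hump amplitudes (60 / 34 / 40 µm) are chosen so
peak sector thickness is plausible for each group; only the circle average
is a calibration target. Between-phantom variability (the \(u\) scale plus
jitter) yields a circle-average SD of roughly 3–4 µm — deliberately milder
than clinical between-eye SDs (11–19 µm), since no per-sector variance
structure is published to emulate; tests therefore validate *means*, not
dispersion.

Rendering stacks three intensity levels — vitreous (0.05), RNFL band
(0.85), deeper retina (0.45) — warped by a slowly undulating internal
limiting membrane, quantizes the band to whole pixels (so the per-column
mask count is always within half an axial pixel of the requested profile),
and multiplies by gamma speckle with shape 4 and unit mean (`Inf` disables
it). Optional artifacts emulate the structures that derail machine
segmentation: a bright detached line above the ILM over a ~30% arc
(epiretinal-membrane-like) and a faint oblique vitreous line
(posterior-vitreous-detachment-like). These are plausibility stand-ins, not
physical models; likewise the speckle is i.i.d. gamma rather than
physically correlated coherent noise, and there are no vessel shadows or
3-D context. Passing tests on phantoms therefore demonstrate the pipeline's
*mechanics* (calibration, geometry, learnability of a band with speckle),
not clinical-grade segmentation performance.

Default geometry is 256 A-scans × 256 axial pixels at 3.87 µm/px (the
nominal Spectralis axial sampling; the device itself is not emulated), so
the core tests need no resizing; a 496×768 "Spectralis-like" size exercises
the resize path separately, which keeps resizing concerns out of
segmentation tests.

Seeding: one master integer seed; every phantom, artifact and stage draws
from a child seed derived by splitmix-style 64-bit mixing
(`derive_seed()`), so datasets of any size are reproducible bit-for-bit
across platforms.

```{r phantom}
spec <- phantom_spec(group_preset = "control")
spec
profile <- tsnit_profile(spec, seed = 7)
circle_average(profile)
phantom <- render_bscan(spec, profile, seed = 7)
phantom$image
```

## Preprocessing

Speckle is suppressed by grayscale morphological opening followed by
closing with a 3×3 square structuring element: opening removes bright
speckle grains (the dominant OCT artifact), closing then removes dark pits.
The order is a design choice — either composition is idempotent, and the
open-then-close variant attacks the bright grains first. The filter never
widens the intensity range.

Network input is a fixed 256×256 grid. Images no larger than the target are
zero-padded symmetrically (odd margins put the extra pixel at the
bottom/right); larger ones are first downscaled isotropically with bilinear
interpolation so the larger dimension equals 256 — scaled dimensions use
ceiling, so a 496×768 scan becomes 166×256 before padding — then padded.
Whether clinically acquired scans were downscaled before padding or cropped
natively small is ambiguous in the source description ("zero padding" alone
cannot produce 256×256 from 496×768); this package handles both and records
the exact transform in a `scale_info` object, which inverts the mapping so
predicted masks return to native dimensions (nearest-neighbour on the way
up, keeping masks strictly binary).

## The segmentation network

The U-Net uses the standard encoder–decoder with skip connections: per
level two 3×3 convolutions with rectified-linear activations, 2×2
max-pooling down, 2×2 up-convolutions and channel concatenation up, and a
final 1×1 convolution squashed through a logistic to a per-pixel RNFL
probability. The default filter ladder is (16, 32, 64, 128, 256); with a
256×256 input the deepest feature map is 16×16. Training minimizes binary
cross-entropy with Adam (defaults: learning rate 1e-3, batch 8, 50 epochs —
unspecified upstream, so chosen as ordinary modern defaults and exposed in
`train_config()`), splitting *scans* (never rows of one scan) 80/20 into
training and validation. The binarization threshold defaults to 0.5 and is
a flag.

The forward and backward passes are implemented natively in the package
(RcppArmadillo, im2col convolutions); gradients are verified against
central-difference numerical differentiation in the test suite. A practical
consequence of the native single-threaded implementation is that training
is *always* deterministic given the seeds — there is no nondeterministic
backend mode to opt out of.

Tests train a reduced ladder (8, 16, 32) on 40 phantoms for 20 epochs
(batch 4 — the shorter schedule benefits from more optimizer steps than the
batch-8 default would give) and evaluate 10 held-out phantoms: mean Dice ≥
0.80 and circle-average MAE ≤ 5 µm are asserted; observed values are around
0.98 and 1 µm. These sizes are the package's scaled-down study conditions
for a single-CPU run; they are a property-level analog of clinical
performance, explicitly not a reproduction of it.

## Post-processing and thickness

Predicted masks may contain gaps and speckles. `clean_mask()` fills
interior holes and removes 8-connected components smaller than 25 px (a
free parameter; 25 px at 256-grid scale removes speckle-sized islands
without threatening a plausible band fragment).

Thickness is quantified per A-scan in two ways. The **column** method —
foreground count per column × axial spacing — is exact for the band
geometry (one contiguous vertical run per column) and is the reporting
default. The **Euclidean-distance-transform** method — twice the per-column
maximum of the distance-to-background — is kept as a cross-check: on flat
bands it matches the column method within one axial pixel (exactly `h` for
even heights, `h+1` for odd), but where the band slopes steeply it reads
the *perpendicular* (local) thickness and under-reads columns thicker than
their neighbourhood; on phantoms with ILM undulation deviations up to ~4–5
pixels occur. That bias is inherent to the estimator, which is why column
counting is the default for reported values.

Sector reporting uses the Spectralis-convention TSNIT layout — temporal
315°–45°, superior-temporal 45°–90°, superior-nasal 90°–135°, nasal
135°–225°, inferior-nasal 225°–270°, inferior-temporal 270°–315°, as
half-open spans (named sectors have no published boundaries, so this
conventional layout is a configurable default) — and the global average is
the plain (unweighted) mean over A-scans, an explicit choice over any
device-internal area weighting. Because the six spans partition the circle,
the average equals the 90/90/45×4-weighted sector mean to floating
precision whenever the A-scan count is a multiple of 8. For left eyes the
angular mapping mirrors (\(\theta \mapsto 180^\circ - \theta\)); a subtle
consequence handled explicitly is that mirroring reverses orientation, so
OS membership uses right-closed intervals — this makes the OD temporal
column set map *exactly* onto the OS nasal column set instead of being off
by one column at span boundaries.

```{r thickness}
mask <- clean_mask(phantom$truth$mask)
prof <- thickness_profile(mask, method = "column")
sector_thickness(prof, eye = "OD")
```

## Evaluation

`segmentation_metrics()` computes pixel-wise tp/fp/tn/fn with ground truth
as reference and derives Dice, sensitivity and specificity; two empty masks
score Dice 1.0 by convention, flagged in the result. Metrics are reported
per scan and averaged (matching the per-image framing of clinical reports);
a pooled-pixel mode is behind a flag. `mae()` and `pearson_r()` cover
thickness agreement. Group-level hypothesis testing is intentionally out of
scope — the reports expose per-scan values for external statistics.

## Pipeline and reproducibility

`run_pipeline()` chains generate → preprocess → train/predict →
post-process → thickness → evaluate. Two segmentation arms replace the
network when needed: **oracle** feeds ground-truth masks straight through
post-processing (mirroring a manual-segmentation reference arm, and
enabling exact end-to-end tests: Dice 1.0, sector recovery to quantization
error), and **corrupt** degrades oracle masks with a simulated segmentation
failure (the band zeroed over a random quarter arc), standing in for
error-prone machine segmentation. The corrupt arm's average-thickness MAE
exceeds the oracle arm's by well over 3 µm — the qualitative ordering one
expects between a sound and a failing segmenter.

Every run writes its resolved configuration to YAML; the MD5 of that file
is stamped into every CSV (first line, `# config: <hash>`) and the JSON
summary, so artifacts are traceable to the exact configuration. Re-running
a configuration reproduces all CSVs byte for byte.

Problem sizes used by the test and acceptance runs — 200 phantoms per
calibration preset, 100 oracle-mode phantoms, 40 train/10 test for the
training analog, 50 phantoms for the corruption ordering — are the
package's documented study conditions, sized for a single-CPU desk run.

## Known limitations

* The phantom family is deliberately simple: three intensity levels, one
  band, i.i.d. speckle, no vessels or 3-D context. Performance on phantoms
  upper-bounds nothing about clinical scans.
* The native U-Net trainer is single-threaded CPU code; it is meant for
  the scaled-down experiments here, not for training on clinical corpora.
* The EDT thickness estimator is a cross-check with a known slope bias, not
  the reporting method.
* Sector boundaries and the OS mirroring follow one device convention;
  other devices rotate or re-centre sectors, which is why the layout is
  configurable.
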