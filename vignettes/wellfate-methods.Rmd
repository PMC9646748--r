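---
title: "wellfate: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{wellfate: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it
implements: the statistical and algorithmic model, the tunable
parameters, what the synthetic-data generator does and does not
emulate, and every numerical convention a maintainer would otherwise
have to reverse-engineer. It states no empirical number that the test
suite or `scripts/acceptance.R` does not itself compute.

## 1. The assay and the pipeline

Single cancer stem-like cells sit in ~200 µm agarose microwells and
are imaged in brightfield for 96 h (frame intervals of 30, 40 or 80
minutes are typical). Each frame of each well is classified into one
of four classes — `Single`, `Multiple`, `Death`, `Empty` — and a
temporal decision tree converts each well's class-probability series
into one fate call: `Divided`, `Died` or `AliveQuiescent`, with an
event time. Population curves summarize the cohort. The pipeline
assumes wells arrive pre-cropped (one frame = one well), grayscale,
with strictly increasing timestamps.

## 2. The convolutional classifier (dlba)

Architecture (fixed family, `cnn_config()`):

* 4 convolution layers of 8, 16, 32, 64 filters, 15×15 kernels, same
  padding, each followed by ReLU and a 2×2 max-pool (stride 2);
* flatten → dense(1024) → ReLU → dropout(0.8) → dense(4) → softmax;
* grayscale input, default 176×176.

The parameter count has the closed form
$\sum_i (k^2 c_{i-1} + 1) c_i + (F \cdot u + u) + (u \cdot 4 + 4)$
with $k = 15$, $u = 1024$ and flatten size $F = (s/2^4)^2 \cdot 64$.
At $s = 176$, $F = 11 \cdot 11 \cdot 64 = 7744$ and the total is
exactly 8,541,700. 176 is the only pooling-compatible input size that
reproduces this figure, which is why it is the default; the input size
was otherwise a free choice.

Training choices (none of which are dictated by the architecture):
categorical cross-entropy, Adam (β₁ = 0.9, β₂ = 0.999), batch size 32,
He-style seeded initialization, inverted dropout after the 1024-unit
layer, model selection by best validation accuracy. Images are resized
to the configured input with bilinear interpolation and standardized
per image (z-score); a constant image maps to zeros.

**Learning rate.** The default is 2·10⁻³ rather than the conventional
1·10⁻³. In the short training budgets this package targets (5 epochs ×
~20 minibatches ≈ 100 Adam steps on the scaled-down benchmark),
1·10⁻³ demonstrably underfits (held-out accuracy ~0.85 on cleanly
separable synthetic classes), 2·10⁻³ converges (0.94–0.96 across
seeds), and 3·10⁻³ is unstable. Users training longer on real data may
prefer 1·10⁻³; it is a plain argument of `train_classifier()`.

**Determinism contract.** Weight initialization, shuffling and dropout
masks all derive from the `seed` argument; the C++ numerics are
deterministic. Bit-identical histories are promised only within one
software configuration (BLAS build, thread count) because GEMM
summation order is backend-dependent.

**Why no framework?** The supported R stack carries no deep-learning
framework, so the conv/pool/dense/softmax forward and backward passes
are implemented in RcppArmadillo via im2col, turning every convolution
into a BLAS GEMM. The gradients are verified against numerical
differentiation in the test suite; single-CPU training of the 64×64
configuration takes a few minutes.

## 3. The classical baseline (ccva)

Five-step pipeline: Otsu threshold → segmentation → size/border filter
→ ellipse fit → rule table.

* **Otsu convention.** Between-class variance is maximized over the
  occurring intensity levels; the returned threshold is
  `level* + 0.5`, so the two classes are separated strictly
  (foreground `x < thr`, background `x > thr`). Ties take the lowest
  level; a constant image returns itself flagged `degenerate`, and
  nothing is foreground.
* **Polarity.** Cells are *dark* objects: foreground is
  `image < threshold`. The bright halo ring around a live cell stays
  above threshold and prevents neighboring cells from merging.
* **Connectivity and filters.** 8-connectivity; size bounds are
  inclusive; an object touching the 2 px border margin is removed
  (this eliminates well-rim arcs and half-cropped neighbors).
* **Ellipse and roundness.** Moment-based fit: full axes are
  $4\sqrt{\lambda}$ of the normalized second central moments
  (a +1/12 term accounts for the pixel's own second moment);
  roundness is $4A/(\pi L^2)$ — the ImageJ convention, 1 for a
  circle, ~0.5 for a 2:1 ellipse — clamped to 1 because pixel
  quantization can push a perfect disk marginally above 1. Masks
  under 5 px are rejected (degenerate moments).
* **Decision table.** 0 objects → `Empty`; ≥2 → `Multiple`; 1 object
  larger than `single_area_max_px` → `Multiple` (merged clump);
  1 object rounder than `roundness_min` → `Single`; else `Death`.
* **Calibration.** The defaults (min area 30 px, max 2500 px, single
  max 700 px, roundness ≥ 0.92, margin 2 px) were calibrated once on
  175 synthetic validation wells (mixed clean/degraded at the default
  1 µm/px geometry) — live objects there had roundness ≥ 0.955 and
  dead clumps ≤ 0.887 — and are frozen. They are in pixels of that
  geometry; rescale for other magnifications.

## 4. The temporal decision tree (fate_tracker)

* Frame label = argmax of the 4-vector; exact ties resolve by the
  fixed order `Single > Multiple > Death > Empty`.
* Initial vote over the first 3 labels: any `Multiple` →
  `MultipleAtStart`; else any `Death` → `DeadAtStart`; else all
  `Empty` → `NoCell`; else all `Single` → `SingleCell`. The remaining
  mixed `Single`/`Empty` case is undefined by the stated rules and is
  reported `Ambiguous` (excluded from tracking).
* Division: earliest time by which ≥2 frames have
  `P(Multiple) > 0.9`, at least one `> 0.99`. The event time is the
  timestamp of the frame that completes the rule. Death: earliest
  frame with `P(Death) > 0.5`. All inequalities are strict, exactly as
  stated; a probability of exactly 0.5 (or 0.9, 0.99) never fires.
* Precedence: division is evaluated first over the *whole* series
  ("division, else death, else quiescent"), even if a death-like
  frame precedes the division signature.
* Frames whose argmax is `Empty` after the initial window are ignored
  (a tracked cell cannot vanish from its well). Note this rule is
  belt-and-braces: a frame with `P(Multiple) > 0.9` or
  `P(Death) > 0.5` can never have argmax `Empty`, so ignoring empties
  cannot suppress an event; it documents intent and guards any future
  relaxation of the thresholds.
* Rules are scanned over all frames including the first three; an
  argmax-`Single` initial frame cannot satisfy either rule, so this is
  harmless.
* A practical consequence of the strict `> 0.99` bar: probability
  traces from `oracle_probabilities()` only produce division calls at
  `confidence = 1` (0.99 exactly does not cross a strict threshold).
  That is faithful to the rule, not a defect of the oracle.

Two structural properties follow from the "qualifying frame" form of
the rules and are enforced as property tests: removing frames can only
*lose* event calls (the recall-drops-at-lower-frame-rate behavior),
and raising any threshold can only reduce the number of calls.

## 5. Population dynamics

With $N$ the initial number of tracked single cells:

* cumulative percentage at $t$: $100 \cdot N_{events}(t) / N$;
* windowed rate at $t$:
  $(N_{events}(t) - N_{events}(t - 6\,h)) / N_{living}(t)$, with the
  window half-open $(t-6, t]$ (inclusivity was unstated; half-open
  windows tile the axis without double counting) and the denominator
  evaluated at the *end* of the window, per the formula's subscript.
* The literal formula is per-window; `rate_units = "per_hour"` divides
  by the 6-h width, which is the scale on which real cohorts read
  ~0.03 events/hour. Both modes are provided because the quoted
  per-hour figures are not reproducible from the per-window formula
  without that normalization.
* A window with zero living singles yields `NA`, never a silent 0.
* Conservation — divided + died + living = initial singles — holds
  exactly (integer counts) at every grid point and is asserted in the
  tests.

## 6. The synthetic world

The generator states a world; its defaults are not tuned to make tests
pass.

* **Geometry.** 176 px frames at 1 µm/px (20× emulation; 2 µm/px
  emulates 10×), 200 µm well. The well slightly overfills the frame,
  so its dark rim appears only as border-touching arcs — this
  reproduces pre-cropped chip layouts and means the border filter,
  not the size filter, removes the rim. (The stated "well fits in
  frame" invariant is incompatible with this stated default geometry;
  the constructor instead requires a visible rim arc,
  diameter ≤ √2 · frame.)
* **Appearance.** Unit-range levels: background 0.72, outside-well
  0.55, rim 0.30, live-cell core 0.35, halo 0.88; 16-bit
  quantization. Live cells are disks of radius uniform in [5, 12] µm
  with a 2 px halo ring; dead cells are connected unions of 3–6
  offset sub-blobs at 40% reduced contrast. Degradations are applied
  in the order illumination gradient → Gaussian defocus → Gaussian
  noise; the frozen `"degraded"` preset is a 20%-range gradient,
  2.5 px blur, 2% noise.
* **Kinetics.** Default cohort composition: 28% single-cell wells
  (matching annotated chip cohorts, which run near 0.28), the
  remainder split 45% empty / 55% multiple, dead-at-start 0. Among
  singles, 17% divide and 38% die within 96 h by independent draws.
  Event times are uniform on (0, 96 h] by default — the simplest
  documented law — with a truncated-exponential `"constant_hazard"`
  mode whose 96-h incidence equals the requested fraction (death
  hazards in real cohorts are roughly constant; division hazards
  decay, which neither law models).
* **Events in renders.** Division replaces the blob by two separated
  daughters from the (grid-snapped) event frame on; death switches to
  the dead-clump morphology; cells perform a small reflected random
  walk and never leave the well.
* **What a green test does not establish.** The renderer has exact
  class-conditional levels, perfectly circular live cells and no
  debris, condensation, well-to-well shape variation or focus drift.
  Classifier accuracies on this world (CCVA ≈ 1.0 clean) are upper
  bounds with no bearing on real-data accuracy; only *relative*
  statements (degradation lowers CCVA accuracy; the CNN can learn the
  classes) transfer. Cohort-level boundary effects are inherent to
  the decision tree, not the generator: an event in frames 1–2 makes
  the well `MultipleAtStart`/`DeadAtStart` (excluded), and a division
  in the final frame leaves only one `Multiple` frame (missed), so
  recovered fractions sit a few tenths of a percent below nominal —
  well inside the binomial noise the acceptance test allows.

## 7. File formats

Stacks are uncompressed little-endian baseline TIFF (8/16-bit
grayscale, one IFD per frame), written with the timestamps and pixel
size embedded as JSON in the first frame's ImageDescription; a
`<stem>_times.csv` sidecar (column `time_min`) is accepted as an
alternative. The reader rejects RGB, compressed and big-endian files
with explicit messages — the supported R stack has no TIFF package, so
the package carries this minimal subset itself, cross-checked against
an independent implementation in the test suite. Tabular outputs are
plain CSV; run metadata is JSON with the seed and configuration echo.

## 8. Known limitations

* The CNN trains on CPU only and at practical speed only for reduced
  inputs (≤ 96 px); full 176 px training of the 8.5 M-parameter model
  is possible but slow.
* `Ambiguous` wells (mixed `Single`/`Empty` start) are excluded rather
  than re-voted; on real data a human would re-inspect them.
* The classical baseline's thresholds are pixel-scale dependent and
  frozen for the default geometry.
* Event-time laws are memoryless or uniform; decaying division
  hazards are not modeled.
* The TIFF subset is deliberately minimal (no tiles, compression,
  BigTIFF, or big-endian).
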