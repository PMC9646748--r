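# wellfate

Label-free cell-fate calling in brightfield microwell time-lapses.

## The problem

The tumorsphere assay probes cancer stem-like cells (CSCs) functionally:
a cell qualifies by surviving and proliferating as a *single* suspended
cell. Microfabricated agarose chips isolate one cell per ~200 µm
microwell, and brightfield time-lapses over 96 h record whether each
single cell divides, dies or stays quiescent. Brightfield is label-free
(no staining artifacts or phototoxicity) but low-contrast: frames suffer
illumination gradients, defocus and debris, so calling fates by eye or
with fixed thresholds does not scale to thousands of wells.

`wellfate` implements the full analysis pipeline for this assay:

1. **Frame classification.** Every microwell frame is classified as
   `Single`, `Multiple`, `Death` or `Empty`, either by
   - a compact convolutional network (**dlba**): four convolution
     layers of 8/16/32/64 filters with 15×15 kernels (same padding),
     each followed by ReLU and 2×2 max-pooling, then a 1024-unit fully
     connected layer with 80% dropout and a 4-way softmax — exactly
     8,541,700 trainable parameters at the default 176×176 grayscale
     input. The network is implemented from scratch on BLAS-backed
     C++ primitives (im2col + GEMM), trained with Adam on categorical
     cross-entropy; or
   - a classical computer-vision baseline (**ccva**): Otsu intensity
     threshold → dark-object segmentation (8-connectivity) → size and
     border filtering → moment-based ellipse fit → a rule table over
     object count, area and roundness `4A/(πL²)`.
2. **Temporal decision tree (fate_tracker).** The first three frame
   labels vote the initial content (all `Empty` → no cell; any
   `Multiple`/`Death` → discarded; all `Single` → tracked). For a
   tracked single cell, a **division** is called when two frames have
   `P(Multiple) > 0.9`, at least one of them `> 0.99`; **else** a
   **death** when any frame has `P(Death) > 0.5`; else the cell is
   alive and non-dividing.
3. **Population dynamics.** Cumulative event percentages
   `%events(t) = 100 · N_events(t) / N_single_cells` and sliding-window
   rates `rate(t) = (N_events(t) − N_events(t − 6 h)) / N_living(t)`
   over 6-h windows (optionally per hour).
4. **Evaluation (metrics).** Confusion matrices, accuracy
   `(TP+TN)/(TP+TN+FP+FN)`, per-class recall `TP/(TP+FN)` and precision
   `TP/(TP+FP)`.
5. **Synthetic data.** A fully annotated microwell renderer (wells,
   rims, halo-rimmed live cells, irregular dead clumps, illumination
   gradients, defocus, noise, division/death events, cohort kinetics)
   so the entire pipeline is testable without any external download.
6. **I/O and CLI.** Minimal 16-bit grayscale multi-frame TIFF
   reader/writer with embedded timestamps, CSV manifests and outputs,
   JSON run metadata, and a `wellfate` command-line tool
   (`generate`, `train`, `classify`, `track`, `dynamics`, `evaluate`).

## Worked example

```r
library(wellfate)

# simulate a 400-well cohort with the reference kinetics:
# ~28% single-cell wells; of those, 17% divide and 38% die within 96 h
k <- cohort_kinetics(n_wells = 400, division_fraction_96h = 0.17,
                     death_fraction_96h = 0.38, frame_interval_min = 30,
                     seed = 20L)
cohort  <- simulate_cohort(k)
probs   <- cohort_oracle_probabilities(cohort, confidence = 1)
records <- track_cohort(probs)
table(records$initial_state)
#> MultipleAtStart          NoCell      SingleCell
#>             168             120             112

series <- compute_dynamics_series(records)
end <- series[series$time_h == 96, ]
sprintf("at 96 h: %.1f%% divided, %.1f%% died, %d of %d still quiescent",
        end$pct_divided, end$pct_died, end$n_living,
        attr(series, "n_single_cells"))
#> "at 96 h: 20.5% divided, 33.9% died, 51 of 112 still quiescent"

mid <- series[series$time_h == 48, ]
sprintf("48 h rates: division %.4f, death %.4f per 6-h window",
        mid$rate_division, mid$rate_death)
#> "48 h rates: division 0.0115, death 0.0115 per 6-h window"
```

The realized fractions wobble around the requested ones (binomial
sampling over 112 tracked singles), and deaths occurring within the
3-frame initial window are — by design of the decision tree — recorded
as `DeadAtStart` rather than `Died`, which is why 33.9% is slightly
below the nominal 38%.

Classifying a rendered frame:

```r
img <- render_well(well_scene_spec(content = "single", seed = 7L))
classify_well_ccva(img)
#> "Single"

build_cnn(cnn_config())
#> <wellfate_cnn> input 176x176, 8,541,700 trainable parameters (untrained)
```

## Command line

```sh
wellfate generate --out data/train --n-per-class 200,200,200,200 --seed 1
wellfate train    --data data/train --input-size 64 --epochs 5 \
                  --out model.rds --seed 1
wellfate classify --data data/test --method ccva --out predictions.csv
wellfate track    --pred predictions.csv --out fates.csv
wellfate dynamics --fates fates.csv --out dynamics.csv
wellfate evaluate --pred predictions.csv --out metrics.json
```

See `vignettes/wellfate-methods.Rmd` for the model assumptions, the
synthetic-data design, numerical conventions and known limitations.
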