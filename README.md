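# hypnoseeg

EEG pipeline for identifying **road hypnosis** — the unconscious driving
state induced by monotonous, highly predictable driving environments — from
frontal EEG, as a two-class problem: road hypnosis (**RH**) vs normal
driving (**ND**).

Driving-study EEG corpora in this area are private, so the package ships a
first-class synthetic-data module that generates labeled recordings with
the statistical structure the analysis assumes, and builds the entire
identification computation on top of it:

* **Synthetic EEG**: 8 frontal 10–20 channels (Fp2, Fpz, Fp1, F4, Fz, F3,
  FC2, FC1) plus two mastoids at 500 Hz; one narrowband oscillatory source
  per canonical band (δ 0.5–4, θ 4–8, α 8–13, β 13–30, γ 30–42 Hz),
  blink/cardiac artifact sources, sensor noise, and a block-alternating
  RH/ND state timeline that scales band amplitudes (default: θ and α ×1.5
  in RH).
* **Preprocessing**: bilateral-mastoid re-referencing; linear-phase
  windowed-sinc FIR filters (low-pass 30 Hz, high-pass 0.1 Hz, notch
  40 Hz) applied forward–backward (zero phase); Morlet CWT comparison
  path.
* **FastICA** (from scratch): PCA whitening, parallel fixed-point updates
  with symmetric decorrelation `W ← (WWᵀ)^(-1/2) W`, automated artifact
  scoring (frontal topography + kurtosis + template matching) and
  component removal `X_corrected = X − A_excl S_excl`.
* **Features**: event-locked epochs 0.2–1.0 s after each annotation (400
  samples), one-sided periodogram `PSD(f) = |X(f)|²/N` (Welch and Hann
  options), half-open band powers.
* **Classifiers** (from scratch, analytic backprop, gradient-checked):
  an EEGNet-style compact CNN — temporal conv (1→16, kernel (1, 51), pad
  (0, 25)) → BN → depthwise conv (16→32, kernel (1, 10), groups 16) → BN →
  ELU → avg-pool (1, 4) → pointwise 1×1 → BN → ELU → dense — plus 2-layer
  RNN/LSTM baselines (input size 1000, hidden size 128); 60/20/20
  stratified hold-out, Adam, early stopping.
* **Evaluation**: confusion matrices with RH positive and
  `ACC = (TP+TN)/n`, `SEN = TP/(TP+FN)`, `SPE = TN/(TN+FP)`,
  `GM = √(SEN·SPE)`; model-comparison tables.
* **Pipeline**: `run_pipeline()` chains electrode location →
  re-reference → filtering → ICA → epoching → features → training →
  evaluation with a hashed manifest, resume support, and exact
  seed-reproducibility.

## Worked example

```r
library(hypnoseeg)

sim <- simulate_recording(synth_config(duration = 602, seed = 11))
sim$recording
#> <eeg_recording> 10 channels x 301000 samples @ 500 Hz (602.0 s)
#>   channels: Fp2, Fpz, Fp1, F4, Fz, F3, FC2, FC1, M1, M2
#>   reference: as-recorded

rec <- rereference(sim$recording)                       # drop mastoids
rec <- apply_filter(rec, design_fir(filter_spec("high-pass", 0.1), 500))
rec <- apply_filter(rec, design_fir(filter_spec("low-pass", 30), 500))
rec <- apply_filter(rec, design_fir(filter_spec("notch", 40), 500))

ica <- ica_fit(rec, n_components = 8, seed = 5)
S   <- ica_sources(ica, rec)
sc  <- identify_artifact_components(ica, S, fs = 500)
head(sc, 2)[, c("component", "score", "frontal_ratio", "kurtosis")]
#>   component    score frontal_ratio kurtosis
#> 1         7 8.041334     0.7567476 30.10817
#> 2         6 3.893224     0.4524642 16.70789
clean <- remove_components(rec, ica, sc$component[sc$flagged])

ep  <- extract_epochs(clean, sim$events)                # 602 x 8 x 400
ds  <- model_dataset(ep)
sp  <- split_dataset(ds$y, seed = 21)
take <- function(i) list(x = ds$x[i, , , drop = FALSE], y = ds$y[i],
                         representation = "time")
fit <- train_model(eegnet_config(), take(sp$train), take(sp$val),
                   max_epochs = 30, patience = 5, seed = 31)
pred <- predict(fit, take(sp$test))
metrics(confusion(ds$y[sp$test], pred$labels))
#> ACC 98.35%  SEN 96.72%  SPE 100.00%  GM 98.35%
```

The two top-scored ICA components are the blink and cardiac sources (high
kurtosis, frontal blink topography) and are excluded, mirroring the usual
two-component rejection in frontal-montage studies. The final line is the
held-out test performance of the CNN on the default two-class fixture; the
RNN and LSTM baselines trained the same way score well below it (see the
model-comparison test), reproducing the expected ordering.

A command-line front end is included:

```sh
inst/cli/hypnoseeg simulate --duration 60 --seed 1 --out sim/
inst/cli/hypnoseeg run --config cfg.yaml --seed 1 --out run/
```

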