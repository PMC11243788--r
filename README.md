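# semgknee

Estimating the knee flexion angle during walking from multichannel surface
electromyography (sEMG), with an attention-based recurrent network.

sEMG reflects muscle activation 20–300 ms before the resulting joint motion,
which makes it a natural control signal for wearable robotics: a knee
exoskeleton that can estimate the angle its wearer *intends* can assist
instead of resist. This package implements the full estimation pipeline for
researchers in rehabilitation engineering and biomechanics:

* **Signal conditioning** — Hampel outlier removal, zero-phase 50–190 Hz
  Butterworth band-pass, windowed rectification, consecutive peak and RMS
  envelope detection, 6 Hz low-pass smoothing.
* **Gait processing** — cycle segmentation at foot-contact events, time
  normalization to 100 samples/cycle, tiling into 20-sample encoder segments
  (40 segments for 8 muscles, 30 for 6), chronological 60/40 train/test
  splits with train-only normalization statistics.
* **The estimator** — an encoder–decoder gated recurrent unit (GRU) network
  with Bahdanau attention (GRU-AM). At decoder step *t*:

  ```
  score(j,t) = Vaᵀ tanh(Ua s(t−1) + Wa h(j))      (alignment)
  α(j,t)     = softmax_j score(j,t)               (attention weights)
  c(t)       = Σ_j α(j,t) h(j)                    (context vector)
  s(t)       = GRU(s(t−1), [ŷ(t−1); c(t)])        (decoder state)
  ```

  trained full-batch with ADAM and a binary cross-entropy loss on min–max
  normalized angles, stopping at training RMSE < 15° or 10,000 epochs. The
  attention-free GRU baseline replaces c(t) with the final encoder state.
  Forward, backward (BPTT through the attention), and the optimizer are
  implemented in base R and verified against finite-difference gradients.
* **Metrics** — per-stride RMSE, Pearson CC, SNR (dB), NRMSE, and the
  convergence rate (slope of first-to-last per-stride RMSE) for sequential
  runs.
* **Protocols** — GRU vs GRU-AM comparison over matched seeds,
  channel-ablation sensitivity ranking, transfer pretraining on the
  six-channel shared muscle set with 10-stride personalization, prequential
  sequential learning every 3 strides, and multi-visit progressive
  adaptation.
* **Synthetic gait generator** — physiologically structured presets
  (`hv8` healthy 8-channel walking, `shared6` transfer scenario, `cp6`
  crouch-gait with low SNR and slow visit-dependent speeds) with stored
  ground-truth envelopes, coupling weights and noise powers, so every stage
  is testable without human data.

## Worked example

```r
library(semgknee)

trial <- synthesize_trial(gait_presets("hv8"), n_strides = 12, seed = 42)
ds    <- prepare_dataset(trial)          # condition -> split -> normalize
ds
#> gait dataset: 12 cycles (7 train / 5 test), 8 channels, L = 100
#>   channels: TA, MG, SL, PL, HL, RF, VL, MH
#>   angle range (train): [1.4, 64.0] deg

fit <- gru_am(ds, hidden = 24, max_epochs = 200, rmse_stop = 6, seed = 1)
summary(fit, ds)
#> GRU-AM (attention) knee-angle estimator
#>   hidden size 24, 8 channels, segment window 20, L = 100
#>   8041 parameters; loss bce; 200 epochs trained (stop: max_epochs)
#>   final training RMSE 12.40 deg
#>   test (n = 5 strides): RMSE 12.76 +/- 1.23 deg, CC 0.694, SNR 1.50 dB
```

The dataset holds 12 synthetic strides of 8-channel EMG envelopes; training
ran its full 200-epoch budget (the RMSE < 6° target was not yet reached at
this small budget) and the held-out strides are estimated to ~13° RMSE with
correlation 0.69 — a deliberately small demonstration; the test-suite
experiments train to convergence. `predict(fit, ds)` returns the estimated
angle trajectories (one row per stride, degrees), `plot(fit, ds)` shows the
training history and an example stride, and `sequential_learn()` /
`progressive_visits()` adapt a fitted model during use.

A command-line interface covering the same pipeline
(`simulate`, `preprocess`, `segment`, `train`, `estimate`, `evaluate`,
`compare`, `ablate`, `transfer`, `sequential`, `visits`) is installed as the
`semgknee` executable; every run writes a `run_config.yaml` snapshot
sufficient to reproduce it.

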