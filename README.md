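# emglab

A workbench for one-dimensional surface electromyography (EMG) signal
processing, built for researchers who want to quantify how
acquisition-side choices — quantizer bit depth, sampling rate, window
geometry — propagate into downstream muscle-activity classification. All
experiments run on a fully specified synthetic generator, so every stage
has ground truth and every result is reproducible from a seed.

## The model at the core

The generator treats surface EMG as wide-sense-stationary colored noise
amplitude-modulated by a muscle activation envelope:

    x(t) = (n(t) * h_BPF(t)) · Σ_k A_k φ(t − τ_k)  +  η(t)

with `n(t)` white Gaussian noise, `h_BPF` a 4th-order Butterworth
bandpass (20–450 Hz), `φ` a Gaussian burst envelope (σ = duration/6,
durations 150–400 ms), `A_k ∈ [2, 4]` mV the envelope peak (the carrier
noise is unit-RMS, so `A_k` is in millivolts), and `η(t)` additive
artifacts: 0.05 mV thermal noise, 0.2 mV / 60 Hz powerline, 0.1 mV /
1.5 Hz drift, and ±3 mV spikes at probability 0.001 per sample. Burst
SNR lands at 15–20 dB.

Around the generator:

* **acquisition** — uniform midtread quantization (3–12 bits over
  ±5 mV) and Kaiser-windowed polyphase rate conversion, with MSE sweeps
  over bit depth and sampling rate and an accuracy-versus-bit-depth
  experiment;
* **windowing** — fixed-length segmentation with fractional overlap and
  exact window-count arithmetic;
* **features** — the 12 Hudgins-style time-domain features per
  600-sample window, a correlation redundancy screen, and a composite
  auto-labeler (RMS > P75 ∧ energy > P80 ∧ std > P70 ∧ zero
  crossings > 20, with a 0.1 mV dead-band);
* **archspec** — analytic shape inference and trainable-parameter
  counting for the benchmarked CNN/LSTM/GRU/GAN-discriminator/RL-encoder
  architectures, no learning framework needed;
* **bench** — stratified 5-fold cross-validation (seed 42) of a fixed
  classifier registry (decision tree, random forest, gradient boosting,
  RBF-SVM, 3-NN, LDA, QDA, voting ensemble);
* **rl** — classification as a single-step MDP (±1 reward, γ = 0.99,
  replay capacity 2000, batch 32, ε: 1.0 → 0.01 over 1000 steps) with a
  small built-in DQN agent.

## Worked example

```r
library(emglab)

tr <- synthesize(gen_config(seed = 1))
print(tr)
#> <emg_trace> 30000 samples at 2000 Hz (15.000 s), 8 bursts
#>   active samples: 15.5%; range [-9.833, 12.493] mV
#>   burst SNR: 19.6 dB
```

15 seconds at 2000 Hz with 8 bursts; the 19.6 dB burst SNR is the pure
burst power over the artifact floor. A full pipeline run — simulate,
10-bit quantization, 600-sample windows, 12 features, composite
auto-labels, stratified 5-fold CV:

```r
rep <- run_pipeline(run_config(
  generator = gen_config(duration_s = 45, n_bursts = 24, seed = 1),
  classifiers = c("knn", "random_forest", "gradient_boosting")))
print(rep)
#> <run_report> seed 1: 150 windows (30 active), label/truth agreement 0.947
#>   knn                accuracy 1.000 +/- 0.000
#>   random_forest      accuracy 1.000 +/- 0.000
#>   gradient_boosting  accuracy 0.993 +/- 0.015
```

150 windows, 30 auto-labeled active; k-NN and random forest classify all
of them correctly, gradient boosting misses one burst-boundary window.
Parameter accounting is analytic:

```r
print(infer(registry("cnn1d")))
#> <shape_report> cnn1d
#>       kind out_len out_channels params
#>     conv1d     600           32    192
#>  maxpool1d     300           32      0
#>    dropout     300           32      0
#>     conv1d     300           64  10304
#>  maxpool1d     150           64      0
#>    dropout     150           64      0
#>    flatten       1         9600      0
#>      dense       1          100 960100
#>      dense       1            1    101
#> total trainable parameters: 970,697
```

A thin command-line wrapper over these functions lives in
`inst/scripts/emglab.R` (`simulate`, `sweep-bits`, `windows`, `features`,
`bench`, `arch` subcommands).

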