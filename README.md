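# pulsetune

Quantitative workflow for studying how *Drosophila* courtship hearing is
tuned to the inter-pulse interval (IPI) of male pulse song. The package
covers the full chain from stimulus to statistic:

* **Stimulus synthesis** — Gaussian-windowed sinusoidal pulses
  (s(t) = A·exp(−t²/2σ²)·sin(2πf_c t), 220 Hz carrier), pulse trains with
  a defined peak-to-peak IPI, sine song (140 Hz), seeded white noise, and
  the two playback protocols used in chaining assays: a continuous-song
  intensity ramp (60→90 dB in 30-s blocks) and intermittent 40-pulse
  trains every 5 s (equal pulse count across IPIs).
* **Chaining behavior** — chaining index CI (3-s chain counts of six
  males summed per 30-s block, max 60), heat maps, summed CI over song
  windows, and the chain-fraction metric (fraction of time ≥ 3 flies
  chain).
* **Calcium imaging** — k-means segmentation of movies into ROIs (soma
  mode: clusters of the time-averaged image; neurite mode: 3-cluster
  k-means on z-scored per-pixel traces), morphological opening cleanup,
  per-ROI traces, most-responding-ROI selection, cubic Savitzky–Golay
  smoothing, and event-locked peak ΔF/F = (F_t − F_b)/F_b with a 1-s
  baseline and 5-s peak window.
* **Tuning curves** — per-fly max normalization, mean ± SEM over IPI or
  intensity, four-parameter logistic fits R(I) = floor + (ceiling −
  floor)/(1 + e^{−s(I−EC50)}) for activation thresholds, and a
  downstream/upstream transfer function with first-order SEM
  propagation.
* **Inference** — Pearson correlation of max-normalized tuning curves
  with an exhaustive/Monte-Carlo label-permutation null, Meng's z-test
  for comparing two dependent correlations, Wilcoxon rank-sum and
  signed-rank tests.
* **Synthetic data** — a ground-truth-known generator (planted Gaussian
  blob ROIs, GCaMP-like double-exponential kernels, planted low-pass /
  band-pass IPI tuning, binomial chaining counts with a planted logistic
  intensity threshold) so every stage is testable by parameter recovery.

## Worked example

Simulate a chaining assay under the intensity ramp and read back the
planted behavioral threshold:

```r
library(pulsetune)

ramp   <- make_ramp_protocol(pulse_train_spec())       # 60 s silence + 13 x 30 s blocks
groups <- simulate_chaining(ramp, n_groups = 14, seed = 20260928)
bh     <- run_behavior_pipeline(groups, ramp)
fit    <- fit_sigmoid(as.numeric(colnames(bh$per_level)),
                      colMeans(bh$per_level))
fit$ec50
#> [1] 70.69  (planted EC50: 70.6 dB)
```

The fitted EC50 is the sound level at which the summed chaining index
reaches half of its ceiling — here recovered to within 0.1 dB of the
planted 70.6 dB threshold with the study-scale 14 groups.

The analysis scripts under `analysis/` run the complete study workflow
on synthetic data (run them in order from the repository root):

```sh
Rscript analysis/01_stimuli.R              # stimulus battery + protocols
Rscript analysis/02_behavior.R             # ramp EC50 + IPI tuning of chaining
Rscript analysis/03_imaging.R              # movie pipeline -> neural tuning + EC50s
Rscript analysis/04_transfer_correlation.R # transfer function + correlations
```

Each writes its tables under `results/` and prints what it found, e.g.
`02_behavior.R` reports the summed-CI peak at the conspecific 35-ms IPI,
and `04_transfer_correlation.R` prints the band-pass transfer function
(ratio 0.80 at 35 ms against ≤ 0.44 at 15–25 ms and ≤ 0.31 at 75–95 ms)
and the correlation report, where the band-pass (downstream-like) curve
matches behavior (r = 0.64, exhaustive permutation p = 0.026 over 9!
label orders) while the low-pass curve does not, and Meng's z confirms
the difference between the two dependent correlations.

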