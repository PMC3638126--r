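# vnresp

Reward-based learning for a virtual neurorobot, driven by emotional
speech. `vnresp` models a closed teaching loop: an agent sees a red or
blue cue card, points left or right with a small spiking network, and a
teacher answers with a *happy* or *sad* spoken phrase. The feedback is
classified from prosody alone — no words — and a happy response gates
spike-timing-dependent plasticity (STDP) that reinforces the pathway
behind the correct action.

The package is aimed at computational-neuroscience and affective-computing
researchers who want a self-contained, reproducible desk-scale version of
this loop: every stage is seeded, synthetic, and testable without
hardware, corpora or a cluster.

## What is inside

- **Synthetic emotional speech** — harmonic-source utterances with
  per-emotion/per-gender F0 statistics (happy above sad, female above
  male), WAV I/O, plus red/blue cue-card images.
- **Pitch tracking** — a two-rate normalized-cross-correlation tracker
  (windows 3361, overlap 2880 samples at 16 kHz; search range 40–600 Hz)
  with dynamic-programming contour selection:
  minimize Σ (1 − NCCF) + 0.35·|log(F0ₜ/F0ₜ₋₁)| over candidate paths.
- **Emotion classification** — utterance endpointing at a 2 s silence
  break, the five-feature prosodic vector (mean/min/max/range of F0, mean
  energy), [−1, 1] feature scaling, and an RBF-kernel SVM
  (K(u, v) = exp(−γ‖u−v‖²), γ = 1/5, C = 1) via the libsvm solver, with
  self-contained JSON model files.
- **Confusion-matrix metrics** — per-class error, the unweighted
  "average error", pooled and headline accuracy, pairwise accuracy; three
  benchmark tables ship as fixtures and reproduce every printed value.
- **Spiking network** — four columns of ten conductance-based LIF
  neurons (VC1/VC2 → PMC1/PMC2, P = 0.5, 0.006 μS) with reward-gated
  exponential STDP, Δt = t_pre − t_post:

      W(Δt) = A₊ · exp(Δt/τ₊)    if Δt < 0   (A₊ = 20, τ₊ = 5 ms, window 50 ms)
      W(Δt) = −A₋ · exp(−Δt/τ₋)  if Δt ≥ 0   (A₋ = 10, τ₋ = 5 ms, window 100 ms)

  applied as Δw = W/100 · w_max per pairing, clamped to [0, 0.012] μS.
- **The behavioral loop** — cue presentation, premotor race-to-threshold
  decisions, spoken (or label) rewards, correlated reward volleys, full
  session logs as tibbles with `tidy()`/`glance()`/`autoplot()` methods.

## Worked example

```r
library(vnresp)

## 1. benchmark confusion table: printed metrics
cm <- paper_confusion("offline")
per_class_error(cm)
#> # A tibble: 4 × 2
#>   class   error_pct
#>   <chr>       <dbl>
#> 1 Happy-M       0
#> 2 Sad-M        13.3
#> 3 Happy-F       5.6
#> 4 Sad-F         0
average_error(cm)      # 4.7  (unweighted mean of class errors, %)
headline_accuracy(cm)  # 95.3 (100 - average error, %)

## 2. synthetic speech -> pitch -> features -> SVM
ds <- make_dataset(10, seed = 42)          # 40 utterances, 20 per emotion
feats <- dataset_features(ds)
sp <- esp_split(feats, 0.5, seed = 42)
model <- esp_train(sp[sp$split == "train", ], train_frac = 0.5, seed = 42)
te <- sp[sp$split == "test", ]
mean(esp_classify(model, te)$.pred == te$label)
#> [1] 0.9

## 3. a 30-trial reward-gated learning session
sess <- run_session(scenario_config(n_trials = 30), seed = 7)
sess
#> <vnr_session: 30 trials, accuracy 0.93, criterion trial 5, 28 rewards>
glance(sess)[, c("criterion_trial", "w_vc1_pmc1_final", "w_vc1_pmc2_final")]
#> # A tibble: 1 × 3
#>   criterion_trial w_vc1_pmc1_final w_vc1_pmc2_final
#>             <int>            <dbl>            <dbl>
#> 1               5            0.012          0.00528
```

The session learns the cue–action rule by trial 5 (the agent answers every
later trial correctly): the rewarded projection VC1→PMC1 saturates at its
0.012 μS ceiling while the crossed projection VC1→PMC2 is mildly
depressed. `autoplot(sess)` draws the weight trajectories;
`tidy(sess)` returns the full per-trial log.

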