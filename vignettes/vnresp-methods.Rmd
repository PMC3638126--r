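---
title: "Methods: prosody-based reward classification and reward-gated spiking plasticity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: prosody-based reward classification and reward-gated spiking plasticity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vnresp)
```

vnresp is a desk-scale model of a closed human-robot teaching loop: a
simulated agent sees a red or blue cue card, points left or right, and is
told "happy" or "sad" by its teacher. The spoken feedback is classified
from prosody alone, and a happy response gates spike-timing-dependent
plasticity (STDP) in a small spiking network, reinforcing the pathway that
produced the correct action. This vignette explains each stage's model,
its assumptions, and the design choices made where the design was open.

## Synthetic emotional speech

No speech corpus ships with the package; the generator stands in for one.
An utterance is a harmonic source — the first ten harmonics of a
fundamental, with 1/k amplitude roll-off — whose instantaneous F0 follows
a contour around the profile mean, scaled to an RMS target, padded with
silence, and mixed with Gaussian noise (default SNR 30 dB). A 10 ms raised
cosine ramp at the onset and offset avoids spectral splatter. Samples are
quantized to the signed 16-bit grid on WAV write, so file round trips are
exact to half a quantization step.

The four default profiles encode the two regularities the classifier
relies on, as observed in emotional-speech corpora: happy speech sits
higher in F0 than sad speech within each speaker group, and female voices
sit above male ones within each emotion. The defaults are happy-female
240 Hz, happy-male 180 Hz, sad-female 170 Hz, sad-male 110 Hz, each with a
15 Hz across-utterance standard deviation. These values reproduce the
*ordering*, which is what the published corpus figures support; exact
corpus statistics are not claimed. Happy profiles use a modulated contour
(a 3 Hz, ±6 % excursion) and sad profiles a gently falling one
(1.02 → 0.98), so the pitch *range* carries class information where the
means of happy-male and sad-female overlap. What passing tests on this
material show is that the pipeline recovers and exploits pitch statistics
correctly — not that it would reach the same accuracy on natural speech,
which adds formants, unvoiced consonants, amplitude dynamics and speaker
variability the generator deliberately omits.

## Pitch tracking

The tracker is a two-rate normalized-cross-correlation (NCCF) design with
dynamic-programming contour selection. Windows are 3361 samples with 2880
samples of overlap (hop 481 ≈ 30 ms at 16 kHz) — the figures are read as
sample counts, the only reading consistent with a 16 kHz system. The
signal is decimated by 8 (FIR anti-aliasing via the signal package) for a
coarse candidate pass over lags covering 40–600 Hz; candidates are then
refined on the full-rate signal within ±(q/2 + 4) lags of each coarse
peak *and of each coarse peak's half lag*. The half-lag windows matter:
at 2 kHz a 350 Hz period is ~5.7 samples, quantized so badly that the
true peak can survive the coarse pass only as its first subharmonic, and
without the extra windows the tracker octave-locks on high tones.

Peak lags get parabolic interpolation for sub-sample resolution. Each
candidate's score is its NCCF value minus `octave_bias` (default 0.02)
per octave of lag above the shortest searched lag — a perfectly periodic
signal correlates equally at its period and at every multiple, so some
tie-breaking pressure toward the shorter lag is required; making the
penalty logarithmic in lag gives every octave step the same cost at every
pitch. Exact score ties break toward the lower frequency. Each frame also
carries an explicit unvoiced candidate scored `1 - best_peak`.

The contour is the exact minimizer of summed local costs `1 - score` plus
transition costs: `0.35 * |log(f0_t / f0_t-1)|` between voiced frames and
a flat 0.2 for voicing switches. Optimality is verifiable by exhaustive
path search on short inputs, and the test suite does so. Voicing
additionally requires the frame energy to clear a dynamic threshold:
twice the 10th percentile of all window energies. That percentile rule
presumes the stream contains silence — true for utterances bounded by
pauses, which is the operating regime; a stream of wall-to-wall speech
would be mis-gated. On seeded synthetic tones and glides between 80 and
400 Hz the median per-window relative error is on the order of 0.01 %
with no octave errors (the acceptance script recomputes this).

## Endpointing, features, classification

A window counts as speech if its energy exceeds the dynamic threshold;
sub-threshold windows are discarded. An utterance closes when two seconds
of consecutive non-speech accumulate — 67 windows at the default hop —
and shorter internal gaps do not split it. Each utterance yields five
features: mean, minimum, maximum and range of F0 over its voiced windows,
plus mean energy. Energy is kept as linear RMS; nothing downstream
benefits from a log transform at this feature count.

Features are scaled linearly to put the training range onto [-1, 1],
with parameters frozen from the training split only; test vectors beyond
the training range extrapolate rather than clip, matching common
margin-classifier practice. Classification is a support vector machine
with an RBF kernel, trained by the libsvm solver (via e1071) with
`gamma = 1/5` (one over the feature count) and `cost = 1`; the paper-side
protocol fixes no hyperparameters, so the libsvm defaults are kept and a
small cross-validated grid search (`esp_tune()`) is provided but off the
default path. The package evaluates the one-vs-one decision rule itself
from the stored support set, which is why a model saved as JSON and
reloaded reproduces predictions exactly. Train/test splits are stratified
by class under a seed; the historical train fractions (33 % offline, 50 %
live) are carried as manifest metadata.

On the synthetic benchmark (default profiles, 20 utterances per emotion,
50/50 split, 20 seeds) held-out accuracy is at or near 100 %, i.e. in the
same regime as the 95.3 %/98.7 % reported for corpus and live recordings
— but the synthetic corpus is much easier than natural speech, so this
demonstrates pipeline correctness, not expected field accuracy.

## Confusion-matrix conventions

Three benchmark confusion tables ship as fixtures. Two accuracy readings
coexist deliberately: `pooled_accuracy()` is trace over total (the
human-listener benchmark's 88.6 %), while `headline_accuracy()` is 100
minus the *unweighted* mean of per-class errors — the only reading that
reproduces 4.7 % from rows of 0, 13.3, 5.6 and 0 %, and hence the 95.3 %
and 98.7 % system figures. All percentages round half-up to one decimal
(1.25 prints as 1.3). When all row sums are equal the two error readings
coincide, as the human table shows at 11.4 %.

## The spiking network

Four columns of ten conductance-based leaky integrate-and-fire neurons:
VC1/VC2 (visual cortex, red/blue) project to PMC1/PMC2 (premotor,
left/right) with independent 50 % connectivity at 0.006 uS; there are no
recurrent or within-area connections. The matched projections
(VC1→PMC1, VC2→PMC2) carry full STDP; the crossed projections are
depression-only. Neuron parameters are not constrained by the source
architecture description, so standard cortical LIF values are used:
membrane tau 20 ms, rest and reset -65 mV, threshold -50 mV, refractory
2 ms, synapse tau 5 ms, excitatory reversal 0 mV, leak 0.025 uS.
Integration is exponential Euler at dt = 0.1 ms; conductances decay
exponentially and spikes increment the target's conductance by the
synaptic weight on the following step.

The premotor columns receive a private background Poisson drive (150 Hz
per neuron at 0.006 uS) calibrated so their idle rate sits near 4 Hz,
the baseline regime of the reference architecture. The visual columns
are stimulus-driven and silent at rest — a deliberate choice: with
tonically active visual columns, background coincidences drive slow
weight drift on every projection, and no parameter setting then keeps
the non-rewarded projections near their initial strength.

STDP follows the exponential rule with `delta_t = t_pre - t_post`:
pre-before-post potentiates by up to A+ = 20, post-before-pre depresses
by up to A- = 10, both decaying with tau = 5 ms inside pairing windows
of 50 ms (potentiation) and 100 ms (depression), edges inclusive; the
boundary `delta_t = 0` lands on the depression branch. The printed
piecewise form this implements is adopted with the sign convention that
makes causal (pre-then-post) pairs potentiate; the opposite orientation
would make the learning task unlearnable. A is read as percent of the
maximum conductance per pairing event: `dw = delta/100 * w_max`, with
`w_max = 0.012 uS` (twice the initial weight), and weights clamp to
`[0, w_max]` after every pairing. Pairing is nearest-neighbor (each new
spike pairs once with the most recent partner spike inside the window);
an all-pairs variant exists as a config switch. `stdp_replay()`
recomputes all weight changes chronologically from the spike log alone
and is required by the tests to agree with the incremental bookkeeping to
floating-point accuracy.

## The behavioral loop

A trial presents the cue as an aggregate 2 kHz Poisson drive onto the
cued VC column for up to one second. The premotor decision is the first
moment the running spike-count difference between PMC1 and PMC2 reaches
15; PMC1 wins → point left (red ball), PMC2 wins → point right (blue
ball); no crossing inside the timeout → no action. The threshold trades
decision speed against noise: lower values let a learned network
occasionally cross on the wrong side early in the window, which breaks
the stability of learned performance.

Feedback is happy exactly when the decision matches the cue. A happy
response enables plasticity for 500 ms while *correlated volleys* are
delivered: a periodic shared event stream (4 Hz) drives the cued VC
column with a suprathreshold 0.05 uS event (synchronous, zero jitter) and
the chosen PMC column with 0.03 uS events delayed 2–6 ms — emulating the
correlated visual and proprioceptive input that accompanies the rewarded
pointing action. VC leads PMC, so pairings on the matched projection are
causal and strongly potentiating, while the crossed projection sees the
cue column's volleys only *after* its own evoked spikes and, being
depression-only, takes no update from them. Periodic rather than Poisson
volley timing matters: Poisson event streams occasionally cluster two
volleys within the 100 ms depression window, and those clusters dominated
crossed-projection drift in Poisson-driven experiments. Five rewarded cue
trials saturate the matched projection near `w_max` while the crossed
projection stays within a few percent of its initial strength, an
order-of-magnitude asymmetry.

A sad response, by default, enables *depression-only* plasticity with the
volley order reversed (chosen PMC leads, cue VC trails), so every pairing
lands on the depression branch and weakens the pathway that produced the
wrong action. The alternative — sad means no reward and no plasticity —
is available (`sad_depresses = FALSE`) but was found insufficient on its
own: random wiring draws give one premotor column a structural advantage,
and without a corrective force roughly half of the sessions never learn
the disfavored cue. With depression enabled, all of 20 seeded 30-trial
sessions reach criterion (five consecutive correct decisions with no
later error), with a median criterion trial around 6 — consistent with
the four-to-five-trial learning reported for the original closed-loop
experiment. Evoked premotor rates on rewarded pathways grow well beyond
1.5-fold while idle rates stay within a few percent, and disabling
plasticity altogether leaves decided-trial accuracy at chance.

The spoken-reward path can replace labels end to end
(`reward_source = "audio"`): each trial synthesizes a happy or sad
utterance, classifies it through the full pitch/feature/SVM path, and
rewards on the predicted label. With the well-separated default profiles
the classifier is error-free, so the reward sequences match the
label-driven ones exactly; the tests assert this equivalence.

## Problem sizes and reproducibility

Every stochastic element — wiring, Poisson drives, volley jitter, cue
order, synthesis noise, splits — draws from R's RNG under named seeds, so
sessions and datasets are bit-reproducible. The shipped evaluations use
desk-scale sizes chosen to keep variance low at interactive runtimes: 50
tones for the pitch benchmark, 20 seeds by 40 utterances for the
classification benchmark, 20 sessions of 30 trials (plus 20 ablation
sessions and 8 five-reward demonstrations) for the learning benchmark.

## Known limitations

The generator's prosody is far cleaner than natural emotional speech;
corpus-level accuracies are not reproducible without the corpus, and the
benchmark here substitutes a correctness check at desk scale. The
dynamic energy threshold assumes silence is present in the stream. The
network has no inhibition, so the unchosen premotor column cannot be
actively suppressed; the printed baseline firing rates of the reference
system depended on simulator internals that are not published, and are
matched only qualitatively (a ~4 Hz idle premotor rate). The reward
volley protocol is this package's concrete realization of "correlated
inputs between the activated visual column and the correctly chosen
premotor column"; other realizations (e.g. rate-modulated drives) trade
learning speed against crossed-projection drift differently.
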