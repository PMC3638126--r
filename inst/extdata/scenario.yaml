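# Default closed-loop experiment: two-choice color-cue pointing task with
# spoken-reward-gated plasticity. Values mirror the package defaults.

scenario:
  decision_threshold: 15      # premotor spike-count difference
  decision_timeout: 1000      # ms
  reward_duration: 500        # ms
  cue_drive: 2000             # Hz, aggregate Poisson onto the cued VC column
  reward_drive: 4             # Hz, periodic correlated reward volleys
  reward_vc_weight: 0.05      # uS per volley event, VC column
  reward_pmc_weight: 0.03     # uS per volley event, chosen PMC column
  sad_depresses: true
  criterion_run: 5
  reward_source: labels

network:
  n_per_group: 10
  connection_probability: 0.5
  initial_weight: 0.006       # uS
  w_max: 0.012                # uS
  dt: 0.1                     # ms
  background_rate: 150        # Hz per premotor neuron
  background_weight: 0.006    # uS
  seed: 1

lif:
  membrane_tau: 20            # ms
  rest_potential: -65         # mV
  threshold: -50              # mV
  reset_potential: -65        # mV
  refractory: 2               # ms
  excitatory_reversal: 0      # mV
  synapse_tau: 5              # ms
  leak_conductance: 0.025     # uS

stdp:
  a_plus: 20                  # percent of max conductance
  a_minus: 10
  tau_plus: 5                 # ms
  tau_minus: 5                # ms
  window_plus: 50             # ms
  window_minus: 100           # ms

pitch:
  window_size: 3361           # samples at 16 kHz
  overlap: 2880
  f0_min: 40                  # Hz
  f0_max: 600                 # Hz
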