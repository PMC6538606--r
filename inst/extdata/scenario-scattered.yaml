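# Example simulation scenario: spatially scattered sources.
# Every field of the scenario is a key; active_subrois may be omitted, in
# which case the sets implied by `type` are realized (sub-ROIs 1, 4, 7
# in both ROIs for the scattered layout).
type: scattered
n_subjects: 8
n_subrois: 9
n_epochs: 50
epoch_window: [-0.25, 0.75]
signal_window: [0.2, 0.4]
freq_set: [15, 16, 17, 18, 19, 20]
q0: 10
signal_scale: 0.08
noise_fraction: 0.3
sampling_rate: 600
noise_slope: 1
noise_shared: 0.2
noise_alpha_bump: 20
noise_beta_bump: 10
noise_scale: 0.017
phase_lag: 0
seed: 42
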