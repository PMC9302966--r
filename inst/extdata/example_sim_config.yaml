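n_participants: 2.0
n_studies: 1.0
words:
- bed
- head
n_trials: 12.0
p_perturbed: 0.5
shift_mean_mels: 125.0
shift_sd_mels: 0.0
baseline_f1_mels: 740.0
baseline_participant_sd_mels: 45.0
baseline_word_sd_mels: 15.0
onset_offset_mels: -80.0
transition_tau_ms: 30.0
noise_trial_sd_mels: 30.0
noise_sample_sd_mels: 20.0
noise_smooth_ms: 25.0
comp_gain_mean: 0.05
comp_gain_sd: 0.08
adapt_gain_mean: 0.015
adapt_gain_sd: 0.04
gain_correlation: 0.4
comp_latency_ms: 120.0
comp_rise_ms: 80.0
duration_meanlog: 5.19
duration_sdlog: 0.15
short_vowel_frac: 0.0
short_vowel_range_ms:
- 60.0
- 99.0
min_post_up: 1
min_post_down: 1
min_baseline_adapt: 1
step_ms: 10.0
seed: 42.0
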