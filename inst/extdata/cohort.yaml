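# Default synthetic cohort: the walkway study conditions
n_subjects: 12
walkway_length: 30        # m
step_height: 0.075        # m
mean_speed: 1.38          # m/s
sd_speed_between_subjects: 0.10
cv_speed_between_trials: 0.05
cv_step_noise: 0.022
trials_per_condition: 4
sample_rate: 100          # Hz
base_step_length: 0.72    # m at mean_speed
step_length_exponent: 0.42
drift_rms: 0.02           # m/s^2
dwell_duration: 0.12      # s
swing_peak_height: 0.05   # m
rng_seed: 1
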