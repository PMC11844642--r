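# Type-I-error and power grid with a clean (treatment-unaffected) reference
# gene: 5 vs 5 samples, unit-variance margins, alternative target shift of
# 2 SD, across three target-reference correlations and three margin shapes.
rhos: [0.0, 0.5, 0.9]
shapes: [gaussian, right_skewed, left_skewed]
n_per_group: 5
reference_effect: 0.0
target_effect: 2.0
alpha: 0.05
n_reps: 10000
seed: 20260921
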