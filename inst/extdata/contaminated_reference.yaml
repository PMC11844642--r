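# Same grid with a contaminated reference gene: the treatment shifts the
# reference CT by one standard deviation, so only the reference-free dCT
# test stays calibrated at every correlation.
rhos: [0.0, 0.5, 0.9]
shapes: [gaussian, right_skewed, left_skewed]
n_per_group: 5
reference_effect: 1.0
target_effect: 2.0
alpha: 0.05
n_reps: 10000
seed: 20260921
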