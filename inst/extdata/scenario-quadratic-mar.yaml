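# Linear-quadratic design, normal X, MAR missingness in X (70% observed),
# evaluation scale n = 200 with 1000 replicates.
analysis: quadratic
x_dist: normal
mechanism: MAR
r_squared: 0.5
n: 200
reps: 1000
M: 5
K: 5
seed: 1
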