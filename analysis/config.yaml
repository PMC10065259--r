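# Workflow configuration for the demonstration analysis. Problem sizes are
# kept moderate so the whole workflow runs in minutes on one CPU; the
# statistical protocol (filter, TMM/cpm, PQN, variance cap, ensemble with
# ELBO-based best-per-K selection, elbow rule, association tests) is the
# full one.
filter_min_cpm: 5
filter_min_frac: 0.10
top_k_genes: 200
thresholds: [0.02, 0.0457, 0.0714, 0.0971, 0.1229, 0.1486, 0.1743, 0.20]
seeds_per_threshold: 5
k_init: 10
tol: 1.0e-6
max_iter: 2000
elbow_delta: 0.01
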