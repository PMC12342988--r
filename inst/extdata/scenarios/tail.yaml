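# Tail-effect survival scenario: log-hazard driven by the upper-tail
# functional (beta* = 5 on p > 0.7) of log-transformed intensities;
# subject-level scale heterogeneity dominant, ~30% censoring.
n_subjects: 300
clusters_per_subject: 4
cells_per_cluster: 200
sdlog: 0.5
tau: 0.2
kappa: 0.2
scale_sd: 0.6
censor_rate: 0.3
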