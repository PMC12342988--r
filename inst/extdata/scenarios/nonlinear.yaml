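# Nonlinear-effect scenario: gaussian outcome linked to
# integral of Q_i(p) * (1 + p).
n_subjects: 200
clusters_per_subject: 4
cells_per_cluster: 200
sdlog: 0.5
tau: 0.5
kappa: 0.2
sigma_rel: 0.1
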