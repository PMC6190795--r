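# Demonstration pipeline configuration: a deliberately small simulated
# study so the full simulate -> fit -> diagnostics -> PTA chain completes
# in well under a minute on one CPU.
output_dir: cefapop-demo
seed: 20
n_subjects: 14
omega_structure: diagonal
n_bootstrap: 3
vpc_reps: 30
pta_n_subjects: 400
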