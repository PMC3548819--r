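# Small demonstration configuration: coarse parameter set b with a reduced
# ensemble and Monte Carlo budget, suitable for quick runs.
set: b
n_conformations: 2
equilibration_attempts: 20000
n_walkers: 2000
target_fraction: 0.87
seed: 1
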