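# Null scenario: cohorts drawn from identical kinetics; used for type-I
# error calibration of the per-protein tests.
name: null
n_proteins: 1000
turnover_scale: 1.0
label_days: 6
seed: 7
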