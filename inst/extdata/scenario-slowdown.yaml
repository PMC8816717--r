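# Presymptomatic beta-amyloidosis hippocampus scenario: a uniform global
# slowdown of protein turnover (-6.1% incorporation) with steady-state
# abundance unchanged, 1392 proteins quantified in both cohorts.
name: global-slowdown
n_proteins: 1392
turnover_scale: 0.939
label_days: 6
seed: 113
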