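# Symptomatic amyloidosis cortex scenario: a uniform global increase of
# protein turnover (+15.7% incorporation), 721 proteins.
name: global-speedup
n_proteins: 721
turnover_scale: 1.157
label_days: 6
seed: 548
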