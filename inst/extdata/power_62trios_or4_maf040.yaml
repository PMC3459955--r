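# 62-trio design, alternative scenario: 62 trios,
# risk-allele frequency 0.04, imprinting relative risk 4
maf: 0.04
n_trios: 62
rr_imprinting: 4
baseline_risk: 0.005
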