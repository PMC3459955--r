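# 62-trio design, primary scenario: 62 trios, risk-allele
# frequency 0.075, imprinting relative risk 3
maf: 0.075
n_trios: 62
rr_imprinting: 3
baseline_risk: 0.005
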