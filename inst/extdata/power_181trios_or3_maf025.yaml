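# 181-trio design: 181 trios, risk-allele frequency 0.025,
# imprinting relative risk 3, no other effects
maf: 0.025
n_trios: 181
rr_imprinting: 3
baseline_risk: 0.005
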