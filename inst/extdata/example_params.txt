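# element  epsilon(kcal/mol)  sigma(A)  born_radius(A)
H   0.0157  2.471  1.20
C   0.0860  3.400  1.70
N   0.1700  3.250  1.55
O   0.2100  2.960  1.52
S   0.2500  3.564  1.80
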