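3
toy ligand
C    0.000000    0.000000    0.000000
N    1.350000    0.000000    0.000000
O    2.050000    1.150000    0.000000
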