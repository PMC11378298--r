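toy ligand
  pocketedda
synthetic three-atom probe
  3  2  0  0  0  0  0  0  0  0999 V2000
    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.3500    0.0000    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0
    2.0500    1.1500    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0
  2  3  1  0
M  END
$$$$
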