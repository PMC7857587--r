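toy46:
  weights: toy46_weights.txt
  topology: toy46_top.pdb
  trajectory: toy46_conformers.pdb
  triad:
  - 'N'
  - CA
  - C
  nitroxide:
  - N1
  - O1
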