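Place locally obtained copies of deposited reference data here to enable
the structure-dependent acceptance tests:
  5xg2.pdb  4rsj.pdb  5xg3.pdb  1xex.pdb  screen_efficiencies.tsv
These files are not redistributed with the package.
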