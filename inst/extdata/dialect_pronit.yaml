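# ProNIT-style protein-nucleic-acid affinity table: dissociation constants
# in molar, temperature in degrees Celsius; a directly reported ddG (if
# present) takes precedence over the KD pair.
task: protein-DNA
sep: "\t"
temperature_unit: C
columns:
  structureId: pdb
  chain: chain
  mutation: mutation
  kd_wt: kd_wild
  kd_mt: kd_mutant
  ddG: ddG
  pH: pH
  temperature: T
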