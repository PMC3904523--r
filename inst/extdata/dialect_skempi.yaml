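# SKEMPI-style protein-protein affinity table: wild-type and mutant
# dissociation constants in molar, temperature in Kelvin.
task: protein-protein
sep: "\t"
temperature_unit: K
columns:
  structureId: pdb
  chain: chain
  mutation: mutation
  kd_wt: affinity_wt_M
  kd_mt: affinity_mut_M
  temperature: temperature_K
  pH: pH
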