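# canonical export dialect written by writeMutationTable(): temperatures
# already in Kelvin, affinities in molar, ddG in kcal/mol.
task: stability
sep: "\t"
temperature_unit: K
columns:
  structureId: pdb
  chain: chain
  mutation: mutation
  ddG: ddG
  kd_wt: kd_wt
  kd_mt: kd_mt
  pH: pH
  temperature: temperature_K
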