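# ProTherm-style stability table: one row per measurement, measured ddG in
# kcal/mol, temperature reported in degrees Celsius.
task: stability
sep: "\t"
temperature_unit: C
columns:
  structureId: pdb
  chain: chain
  mutation: mutation
  ddG: ddG
  pH: pH
  temperature: T
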