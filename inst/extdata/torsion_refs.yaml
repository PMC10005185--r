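# Example reference torsion statistics for the sulfonamide linker.
# Values are user-supplied summary statistics (e.g. means over identical
# fragments from a licensed small-molecule structure database); the ones
# below are illustrative defaults for the shipped template, not database
# values.
refs:
  alpha: 70
  beta: -95
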