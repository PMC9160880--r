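# Synthetic-default fragment library for the TOY_CMP network preset.
# Amino-acid-style fragments with TBDMS-like derivatization formulas,
# intended for simulation and testing; not a published fragment list.
fragments:
- id: FragP
  amino_acid: ala-like
  precursors:
  - met: P
    positions:
    - 1
    - 2
  formula:
    C: 8.0
    H: 26.0
    'N': 1.0
    O: 1.0
    Si: 2.0
- id: FragG
  amino_acid: ser-like
  precursors:
  - met: G
    positions:
    - 1
    - 2
    - 3
  formula:
    C: 14.0
    H: 36.0
    'N': 1.0
    O: 2.0
    Si: 2.0
- id: FragR
  amino_acid: gly-like
  precursors:
  - met: R
    positions:
    - 1
    - 2
  formula:
    C: 8.0
    H: 26.0
    'N': 1.0
    O: 1.0
    Si: 2.0
- id: FragT
  amino_acid: glu-like
  precursors:
  - met: T
    positions:
    - 1
    - 2
    - 3
  formula:
    C: 14.0
    H: 36.0
    'N': 1.0
    O: 2.0
    Si: 2.0
- id: FragT23
  amino_acid: glu-like
  precursors:
  - met: T
    positions:
    - 2
    - 3
  formula:
    C: 8.0
    H: 26.0
    'N': 1.0
    O: 1.0
    Si: 2.0
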