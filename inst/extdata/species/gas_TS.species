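# Synthetic example stationary point (not from any electronic-structure
# calculation): gas-phase-like transition state with a single imaginary
# mode, used in examples and I/O tests.
schema_version: 1
label: gas_TS
role: transition_state
energies:
  bhlyp: -186.123456789012
  pbe: -186.101234567890
wavenumbers:
  - "1000i"
  - 450.0
  - 862.5
  - 1210.0
  - 2120.0
  - 3310.0
geometry:
  - [N, 0.0, 0.0, 0.0]
  - [C, 1.16, 0.0, 0.0]
  - [H, 2.18, 0.3, 0.0]
mobile_mask: [0, 1, 2]
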