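schema_version: 1
description: >
  Dimethylammonium-like permeation: two-component voltage gating (plateau
  in the normalized tail curve around 0 mV), outwardly rectifying
  macroscopic I-V.  Component midpoints/slopes follow the wild-type
  two-Boltzmann activation parameters (z1 = 1.71 at -93.64 mV, z2 = 1.07
  at +130.73 mV); the component weight A is a free parameter set to 0.6.
po_law: {A: 0.6, V_mid1: -93.64, k1: 14.866, V_mid2: 130.73, k2: 23.758}
rate_law: {a0: 0.5, za: 0.2, b0: 0.8, zb: 0.2}
perm: {g_plus: 15.0, g_minus: 60.0, V_s: 60.0}
"N": 10000
sigma_o_over_i: 0.1
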