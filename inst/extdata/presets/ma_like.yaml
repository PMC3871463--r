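schema_version: 1
description: >
  Methylammonium-like permeation: outwardly rectifying macroscopic I-V
  driven by a strongly voltage-dependent Po; mild open-pore rectification.
po_law: {A: 1.0, V_mid1: 30.0, k1: 35.0, V_mid2: 30.0, k2: 35.0}
rate_law: {a0: 1.0, za: 0.2, b0: 1.0, zb: 0.2}
perm: {g_plus: 20.0, g_minus: 30.0, V_s: 60.0}
"N": 10000
sigma_o_over_i: 0.1
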