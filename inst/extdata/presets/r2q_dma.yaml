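schema_version: 1
description: >
  R2Q mutant (tandem construct) in symmetrical DMA+: two-Boltzmann
  activation with z1 = 1.04 (V_mid1 = -53.01 mV) and z2 = 0.98
  (V_mid2 = +120.37 mV); weight A = 0.6.
po_law: {A: 0.6, V_mid1: -53.01, k1: 24.443, V_mid2: 120.37, k2: 25.940}
rate_law: {a0: 0.5, za: 0.2, b0: 0.8, zb: 0.2}
perm: {g_plus: 15.0, g_minus: 60.0, V_s: 60.0}
"N": 10000
sigma_o_over_i: 0.1
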