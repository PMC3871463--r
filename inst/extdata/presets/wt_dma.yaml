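schema_version: 1
description: >
  Wild-type channel in symmetrical DMA+: two-Boltzmann activation with
  z1 = 1.71 (V_mid1 = -93.64 mV) and z2 = 1.07 (V_mid2 = +130.73 mV);
  weight A = 0.6 (not reported; free parameter of the preset).
po_law: {A: 0.6, V_mid1: -93.64, k1: 14.866, V_mid2: 130.73, k2: 23.758}
rate_law: {a0: 0.5, za: 0.2, b0: 0.8, zb: 0.2}
perm: {g_plus: 15.0, g_minus: 60.0, V_s: 60.0}
"N": 10000
sigma_o_over_i: 0.1
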