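schema_version: 1
description: >
  Ethylammonium-like permeation: strongly outwardly rectifying, slow
  voltage-dependent activation whose bell-shaped tau(V) carries ~0.88
  equivalent charges (za + zb = 0.88).
po_law: {A: 1.0, V_mid1: 60.0, k1: 28.9, V_mid2: 60.0, k2: 28.9}
rate_law: {a0: 0.35, za: 0.44, b0: 0.35, zb: 0.44}
perm: {g_plus: 20.0, g_minus: 30.0, V_s: 60.0}
"N": 10000
sigma_o_over_i: 0.1
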