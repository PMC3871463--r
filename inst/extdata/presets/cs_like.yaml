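schema_version: 1
description: >
  Cs+-like permeation: strongly inwardly rectifying open pore (chord
  conductance ~4x larger at hyperpolarized voltages), Po dropping ~55%
  from +200 to -200 mV, pronounced tail currents.
po_law: {A: 1.0, V_mid1: -160.0, k1: 120.0, V_mid2: -160.0, k2: 120.0}
rate_law: {a0: 0.28, za: 0.15, b0: 0.53, zb: 0.15}
perm: {g_plus: 30.0, g_minus: 120.0, V_s: 60.0}
"N": 10000
sigma_o_over_i: 0.1
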