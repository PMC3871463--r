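schema_version: 1
description: >
  Rb+-like permeation: inwardly rectifying open pore (chord conductance
  ~3x larger at -200 than +200 mV), Po dropping ~25% from +200 to
  -200 mV, deactivation tau in the 0.3-1.2 ms range and faster at
  hyperpolarized potentials.
po_law: {A: 1.0, V_mid1: -400.0, k1: 250.0, V_mid2: -400.0, k2: 250.0}
rate_law: {a0: 0.29, za: 0.15, b0: 0.6, zb: 0.15}
perm: {g_plus: 30.0, g_minus: 90.0, V_s: 60.0}
"N": 10000
sigma_o_over_i: 0.1
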