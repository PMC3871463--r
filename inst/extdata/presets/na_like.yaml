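# Channel-model preset schema v1: po_law (two-Boltzmann equilibrium open
# probability), rate_law (relaxation kinetics), perm (open-pore chord
# conductance), N (channel count), sigma_o_over_i (open-channel noise).
schema_version: 1
description: >
  Na+-like symmetrical permeation: nearly ohmic open pore, high and only
  mildly voltage-dependent open probability, small tail currents.
po_law: {A: 1.0, V_mid1: -400.0, k1: 100.0, V_mid2: -400.0, k2: 100.0}
rate_law: {a0: 2.0, za: 0.05, b0: 2.0, zb: 0.05}
perm: {g_plus: 30.0, g_minus: 30.0, V_s: 60.0}
"N": 10000
sigma_o_over_i: 0.1
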