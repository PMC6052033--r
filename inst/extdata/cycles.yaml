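# Proton-linkage cycles: microscopic pKa of the gating aspartate in the open
# and closed conformations, and the conformational constant K_D of the
# ionized protein. pKa values are inputs (from electrostatics calculations /
# constant-pH simulations reported in the literature); K_H is derived.
NP4:
  pka_open: 4.3
  pka_closed: 8.9
  K_D: 100
NP4_ref:
  pka_open: 4.3
  pka_closed: 8.5
  K_D: 100
NP7_wt:
  pka_open: 4.1
  pka_closed: 6.9
  K_D: 4
NP7_E27Q:
  pka_open: 4.1
  pka_closed: 5.7
  K_D: 4
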