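# Published microscopic rate constants (global fit of CO rebinding at 20 C)
# for NP7 variants at two pH values. Units: s^-1 except k_m2 (M^-1 s^-1).
wt_pH7.5:
  k_m1: 0.60e10
  k_2:  9.0e8
  k_m2: 0.6e8
  k_3:  2.0e3
  k_m3: 1.2e3
  k_c:  3.7e9
  k_mc: 1.4e9
  k_d:  1.6e8
  k_md: 1.4e4
  k_e:  4.5e10
  k_me: 2.5e10
E27V_pH7.5:
  k_m1: 0.2e10
  k_2:  6.4e8
  k_m2: 0.6e8
  k_3:  1.7e3
  k_m3: 1.9e3
  k_c:  2.9e9
  k_mc: 1.9e9
  k_d:  1.8e8
  k_md: 1.4e4
  k_e:  7.0e10
  k_me: 6.5e10
E27Q_pH7.5:
  k_m1: 0.6e10
  k_2:  15.0e8
  k_m2: 0.9e8
  k_3:  20.0e3
  k_m3: 3.0e3
  k_c:  1.7e9
  k_mc: 0.07e9
  k_d:  1.01e8
  k_md: 4.9e4
  k_e:  3.0e10
  k_me: 0.6e10
wt_pH5.5:
  k_m1: 1.4e10
  k_2:  8.2e8
  k_m2: 1.6e8
  k_3:  2.9e3
  k_m3: 4.0e3
  k_c:  0.5e9
  k_mc: 1.2e9
  k_d:  2.1e8
  k_md: 1.2e4
  k_e:  8.0e10
  k_me: 1.9e10
E27V_pH5.5:
  k_m1: 0.32e10
  k_2:  5.6e8
  k_m2: 1.3e8
  k_3:  2.4e3
  k_m3: 1.2e3
  k_c:  2.3e9
  k_mc: 2.4e9
  k_d:  0.93e8
  k_md: 1.2e4
  k_e:  3.7e10
  k_me: 9.0e10
E27Q_pH5.5:
  k_m1: 0.70e10
  k_2:  10.0e8
  k_m2: 1.0e8
  k_3:  21.0e3
  k_m3: 3.0e3
  k_c:  1.3e9
  k_mc: 0.07e9
  k_d:  1.01e8
  k_md: 5.0e4
  k_e:  1.0e10
  k_me: 0.6e10
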