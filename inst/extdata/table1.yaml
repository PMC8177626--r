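schema: saccade3d-plant/1
eye_radius_cm: 7.0
kappa_N_per_m: 6.0
pretension: 0.05
chi_dyn: 0.02
chi_stat: 0.006
eps_stat: 0.01
dt_s: 0.01
substeps: 10
dz_cm: 0.0
via_comove: yes
inertia_kg_m2:
- - 0.0004759
  - -1.0e-06
  - 1.11e-05
- - -1.0e-06
  - 4.316e-04
  - 0.0e+00
- - 1.11e-05
  - 0.0e+00
  - 3.956e-04
muscles:
  MR:
    Q0:
    - -0.7
    - 7.5
    - 0.0
    P0:
    - -32.3
    - 14.0
    - 0.5
    driver: 2
  LR:
    Q0:
    - -0.7
    - -7.5
    - 0.0
    P0:
    - -32.3
    - -14.0
    - 0.5
    driver: 2
  SR:
    Q0:
    - -0.7
    - 0.53
    - 5.3
    P0:
    - -43.6
    - -8.4
    - -7.9
    driver: 1
    X:
    - -20.6
    - -7.5
    - -5.3
  IR:
    Q0:
    - -0.7
    - 0.53
    - -5.3
    P0:
    - -43.6
    - -8.4
    - 12.1
    driver: 1
    X:
    - -20.6
    - -7.5
    - 5.3
  SO:
    Q0:
    - -0.7
    - -0.53
    - 5.3
    P0:
    - -43.6
    - 8.4
    - 12.1
    driver: 3
    X:
    - -15.0
    - 15.0
    - 6.3
  IO:
    Q0:
    - -0.7
    - -0.53
    - -5.3
    P0:
    - -43.6
    - 8.4
    - -7.9
    driver: 3
    X:
    - -15.0
    - 15.0
    - -6.3
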