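# Toy CVFF parameter table -- NON-PHYSICAL values for tests and examples
# only. Wildcard "*" matches any particle tag; tag-specific rows override.
bonds:
  - {i: "*", j: "*", D: 100.0, alpha: 2.0, b0: 1.5}
  - {i: "N", j: "HN", D: 120.0, alpha: 2.2, b0: 1.01}
angles:
  - {i: "*", j: "*", k: "*", H: 50.0, theta0: 109.5}
torsions:
  - {i: "*", j: "*", k: "*", l: "*", H: 1.2, "n": 3, s: 1}
out_of_plane:
  - {i: "*", j: "*", k: "*", l: "*", H: 4.0}
cross:
  F_bb: 4.0
  F_tt: 1.5
  F_bt: 2.5
  F_ptt: 0.8
  F_xx: 1.0
nonbonded:
  - {type: "*", eps: 0.12, rstar: 3.6}
  - {type: "HN", eps: 0.02, rstar: 2.4}
charges:
  N: -0.30
  HN: 0.30
dielectric: 1.0
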