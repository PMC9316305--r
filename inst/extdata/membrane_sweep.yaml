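# Membrane recipe variant used for the productivity sweeps: the hold-until
# phases are resolved to the upper ends of the observed ranges
# (regeneration 10 MV, re-equilibration 16 MV).
device:
  name: membrane-prototype-1.2mL
  kind: membrane
  stationary_phase_volume_ml: 1.2
  bed_height_mm: 4
  void_volume_ml: 0.0
feed:
  titer_g_per_l: 3.12
recipe:
  load_fraction_of_dbc: 0.8
  phases:
    - {name: equilibration,    volume_mv: 5,  flow_rate_mv_min: 10}
    - {name: load,             volume_mv: .na, flow_rate_mv_min: 5}
    - {name: wash,             volume_mv: 12, flow_rate_mv_min: 10}
    - {name: elution,          volume_mv: 12, flow_rate_mv_min: 5}
    - {name: regeneration,     volume_mv: 10, flow_rate_mv_min: 5,
       hold_rule: {trigger: "pH >= 12.3", extra_volume_mv: 4}}
    - {name: re_equilibration, volume_mv: 16, flow_rate_mv_min: 10,
       hold_rule: {trigger: "pH <= 7.5"}}
yield: 0.947
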