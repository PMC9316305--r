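# Bind-elute cycling recipe for the 1.2 mL protein A membrane prototype.
# Hold-until phases (regeneration: hold until pH >= 12.3 then 4 MV more;
# re-equilibration: hold until pH <= 7.5) are resolved to the fixed volumes
# below (lower ends of the observed 9-10 / 15-16 MV ranges).
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
    - {name: regeneration,     volume_mv: 9,  flow_rate_mv_min: 5,
       hold_rule: {trigger: "pH >= 12.3", extra_volume_mv: 4}}
    - {name: re_equilibration, volume_mv: 15, flow_rate_mv_min: 10,
       hold_rule: {trigger: "pH <= 7.5"}}
load_density_g_per_l: 34.4
yield: 0.947
metadata:
  printed_cycle_time_min: 9.6
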