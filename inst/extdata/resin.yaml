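# Bind-elute recipe for the 1 mL packed protein A resin column (volumes in
# column volumes CV, flow rates in CV/min). The printed average cycle time
# (100.4 min) is not exactly recoverable from these phase entries and is
# carried as metadata, consumed as data where needed.
device:
  name: resin-column-1mL
  kind: resin
  stationary_phase_volume_ml: 1.0
  void_volume_ml: 0.0
feed:
  titer_g_per_l: 3.12
recipe:
  load_fraction_of_dbc: 0.8
  phases:
    - {name: equilibration,    volume_mv: 5,  flow_rate_mv_min: 0.5}
    - {name: load,             volume_mv: .na, flow_rate_mv_min: 0.3}
    - {name: wash,             volume_mv: 6,  flow_rate_mv_min: 0.5}
    - {name: elution,          volume_mv: 12, flow_rate_mv_min: 0.5}
    - {name: regeneration,     volume_mv: 2,  flow_rate_mv_min: 0.2}
    - {name: re_equilibration, volume_mv: 6,  flow_rate_mv_min: 0.5}
load_density_g_per_l: 24.3
yield: 0.964
metadata:
  printed_cycle_time_min: 100.4
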