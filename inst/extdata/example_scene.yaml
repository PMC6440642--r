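domain_box_m:
- 4.0
- 3.0
- 2.5
enclosure: ~
ambient_wind_mps:
- 0.5
- 0.0
- 0.0
fans: []
devices:
- position_m:
  - 2.0
  - 1.5
  - 0.5
  schedule:
    breakpoints_h:
    - 0.0
    - 8.0
    rates_mg_s:
    - 0.2000000000000000111022
    - 0.1000000000000000055511
    boost_factor: 2.0
    boost_duration_h: 8.0
  label: CRD-demo
pouches:
- id: near
  position_m:
  - 2.5
  - 1.5
  - 1.0
  level_label: mid
  ring_label: ''
  n_mosquitoes: 20
  control: no
- id: far
  position_m:
  - 3.5
  - 2.5
  - 1.5
  level_label: high
  ring_label: ''
  n_mosquitoes: 20
  control: no
duration_h: 24.0
air_temperature_K: 298.1499999999999772626325
air_pressure_Pa: 101325.0

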