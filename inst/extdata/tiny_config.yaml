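# Minimal end-to-end configuration: 20 agents on a 50 x 50 grid with a short
# 2-day tracking campaign. Intended for smoke tests and quick demos.
world:
  grid_n: 50
  cell_size: 100
  n_municipalities_side: 3
  network_n: 6
  pollutants:
    NO2:
      background: 12.0
      amplitude: 22.0
      noise_sd: 1.5
      n_stations: 6
      edge_nodata_m: 0.0
    PM25:
      background: 12.5
      amplitude: 6.0
      noise_sd: 0.4
      n_stations: 3
      edge_nodata_m: 0.0
      corner_nodata_m: 800.0
n_agents: 20
n_realizations: 5
gps:
  sampling:
    tracker_interval_s: 20.0
    app_interval_range_s: [180.0, 240.0]
    duration_days: 2
  noise_sd: 10.0
  dropout_rate: 0.0
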