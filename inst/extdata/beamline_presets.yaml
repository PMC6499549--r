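# Beamline presets: soft-x-ray single-particle imaging endstation with a
# two-panel pnCCD detector. Distances/gaps per experiment configuration.
beam:
  photon_energy_eV: 800
  peak_fluence_mJ_um2: 0.02
  pulse_energy_mJ: 1.5
  pulse_duration_fs: 170
  repetition_rate_hz: 120
  dumped_fraction: 0.05
presets:
  carboxysome:
    detector_distance_mm: 370
    gap_mm: 5.5
  sucrose:
    detector_distance_mm: 370
    gap_mm: 5.5
  tbsv:
    detector_distance_mm: 259
    gap_mm: 3.3
  tbsv_nominal:
    detector_distance_mm: 250
    gap_mm: 3.3
  rubisco:
    detector_distance_mm: 130
    gap_mm: 3.3
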