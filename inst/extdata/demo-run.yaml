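# Desk-scale synthetic demo: one cross marker on a 96 x 96 px scene at
# 500 fps, idle for the first second, then vibrating at 40 Hz with 2.5 um
# amplitude; amplified 100x over 10-100 Hz and analyzed end to end.
scene:
  width_px: 96
  height_px: 96
  fps: 500
  duration_s: 2
  pixel_pitch_mm: [0.49, 0.46]
  background_level: 0.55
  texture_amp: 0.02
  noise_sigma: 0.005
  supersample: 8
  seed: 7
  markers:
    - id: nose
      center_px: [48, 48]
      arm_length_mm: 10
      arm_width_mm: 2
      contrast: 0.45
      tones:
        - {amplitude_um: 2.5, frequency_hz: 40, phase_rad: 0,
           axis: horizontal, active_from_s: 1}
magnify:
  f_lo: 10
  f_hi: 100
  alpha: 100
gain:
  g: 101
segments:
  - {condition: idle, t_start_s: 0, t_end_s: 1}
  - {condition: scan, t_start_s: 1, t_end_s: 2}
stats:
  n_boot: 500
  n_perm: 499
  block_len_s: 0.1
  baseline_condition: idle
  seed: 1
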