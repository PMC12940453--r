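# Reference acquisition profile: 4000 fps high-speed video of a head
# phantom during a diffusion-weighted acquisition, amplified over the
# 10-1000 Hz band at amplification factor 100, pixel pitch 0.49 (x) /
# 0.46 (y) mm/px, with the 87 s acquisition segmented into b = 0 and three
# diffusion-encoding directions.
input:
  clip: recorded-clip.tiff      # supply the recorded stack
  fps: 4000
  pixel_pitch_mm: [0.49, 0.46]
  markers: []                   # marker geometry of the recorded scene
magnify:
  f_lo: 10
  f_hi: 1000
  alpha: 100
gain:
  g: 101
track:
  search_radius_px: 4
segments:
  - {condition: b0,   t_start_s: 0,  t_end_s: 12}
  - {condition: dir1, t_start_s: 12, t_end_s: 37}
  - {condition: dir2, t_start_s: 37, t_end_s: 62}
  - {condition: dir3, t_start_s: 62, t_end_s: 87}
stats:
  n_boot: 500
  n_perm: 499
  block_len_s: 0.1
  baseline_condition: b0
spectra:
  f_max: 500
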