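{
  "phantom": {
    "kind": "depth_ladder",
    "n_tubes": 3,
    "thickness_mm": 6
  },
  "fx_list": [0, 0.6],
  "camera": {
    "gain": "auto",
    "noise": "poisson",
    "target_peak": 1100
  },
  "n_photons": 2e5,
  "n_emission": 8e5,
  "pixel_pitch_mm": 0.375,
  "seed": 1
}
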