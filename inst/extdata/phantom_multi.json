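{
  "beam": {"wavelength_nm": 640, "waist_mm": 0.45, "ell": 3, "p": 0},
  "phantom": {"d_mm": 8, "n": 1.4, "mus_per_mm": 6, "mua_per_mm": 0.01,
              "g": 0.8},
  "detector": {"nx": 128, "ny": 128, "pitch_um": 40, "na": 0.25},
  "source": "mc",
  "n_ph": 1e6,
  "seed": 1
}
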