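{
  "beam": {"wavelength_nm": 640, "waist_mm": 0.45, "ell": 5, "p": 0},
  "run": {"duration_s": 1500, "fps": 10, "T0": 7.8, "T_room": 21,
          "tau_s": 480, "target_delta_n": 3.69e-4},
  "cuvette": {"d_total_mm": 5.6, "d_wall_mm": 1, "n_glass": 1.5168,
              "n_interior": 1.3616},
  "render": {"n_frames": 32, "n_traj": 8000, "nx": 256, "shot_noise": false},
  "inversion": {"n_grid": 9},
  "seed": 1
}
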