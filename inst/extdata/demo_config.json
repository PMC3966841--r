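{
  "seed": 42,
  "output_dir": "retnathist_demo_out",
  "log_level": "info",
  "stages": ["simulate_erg", "fit_decay", "plan_window",
             "simulate_oct", "segment", "enface"],
  "simulate_erg": { "scatter_sd": 0.2, "n_per_age": 5 },
  "fit_decay": { "floor_policy": "drop", "noise_floor": 5 },
  "plan_window": { "inject_age": 37, "assess_delay": 28, "asym_log": 0.3 },
  "simulate_oct": { "n_eyes_young": 3, "n_eyes_old": 3,
                    "n_lrps": 160, "axial_px": 256 },
  "segment": {},
  "enface": { "n_eyes": 2, "raster_px": 100 }
}
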