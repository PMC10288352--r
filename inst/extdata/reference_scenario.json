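{
  "schema_version": 1,
  "seed": 1,
  "noise": {"rel_sd": 0},
  "kinetics": {
    "Vmax": 1.0,
    "Km": 20.0,
    "Ki": 10.6,
    "Kis": 57.24,
    "S_levels": [6.25, 12.5, 25, 50],
    "I_levels": [0, 5.21, 10.42, 20.83, 41.67],
    "enzyme_substrate_uM": 100,
    "E_levels": [0.25, 0.5, 0.75, 1.0]
  },
  "dose_response": {
    "ic50": 22.97,
    "hill": 1.0,
    "I_levels": [2.0, 3.39, 5.74, 9.72, 16.46, 27.89, 47.23, 80.0]
  },
  "quench": {
    "scheme": {"V0": 2.0, "Va": 0.1, "C_stock": 100, "n_additions": 8},
    "F0": 1000,
    "tau0": 1e-08,
    "eps_ex": 0.010,
    "eps_em": 0.004,
    "temperatures": [
      {"T_K": 298, "Ksv": 188100, "Ka": 16700, "n": 1.183},
      {"T_K": 304, "Ksv": 166100, "Ka": 12100, "n": 1.236},
      {"T_K": 310, "Ksv": 145500, "Ka": 11700, "n": 1.308}
    ]
  },
  "options": {
    "rel_tol": 0.10,
    "origin_tol": 0.05,
    "tau0": 1e-08,
    "diffusion_limit": 2e+10,
    "force_rules": "default"
  }
}
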