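{
  "seed": 5,
  "grid": {"extent": [0, 60, 0, 60], "cell_km": 3},
  "species": {"n": 2, "overlap": 0.4, "hot_frac": 0.1,
              "mu_background": 1, "mu_hot": 20},
  "survey": {"transect_spacing_km": 4.5, "tweedie_p": 1.5, "tweedie_phi": 1},
  "fit": {"n_knots": 25, "year": 2018},
  "hotspots": {"percentile": 0.9, "neighborhood_km": 9},
  "rda": {"n_covariates": 3}
}
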