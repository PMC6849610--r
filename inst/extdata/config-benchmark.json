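{
  "mode": "synthetic",
  "seed": 1,
  "out_dir": "occuedge-output",
  "period_boundary": 1980,
  "grid": { "cell_edge_km": 48.24, "radius_km": 6378.137 },
  "mcmc": { "chains": 3, "iter": 8000, "burn_in": 4000, "thin": 2 },
  "priors": { "fixed_sd": 10, "sigma_scale": 5 },
  "simulation": {},
  "products": { "n_draws": 1000 },
  "write_draws": false
}
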