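{
  "n_ind": 20000,
  "n_var": 5000,
  "n_blocks_ld": 100,
  "ld_r": 0.9,
  "maf_range": [0.05, 0.5],
  "n_items": 12,
  "h2": 0.5,
  "rg_fact": 0.6,
  "item_communality": 0.8,
  "b_low": 0,
  "b_high": 0.8,
  "K": 0.15,
  "ld_window": 60,
  "n_blocks_jk": 200,
  "matrix": "R_delta",
  "quadratic": false,
  "factors": [1, 2, 3],
  "seed": 1,
  "out_dir": "gtaccc_demo_run"
}
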