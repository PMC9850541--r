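{
  "min_genes_per_cell": 200,
  "hvg_mean_min": 0.25,
  "hvg_mean_max": 10,
  "hvg_vmr_cut": 1.2,
  "hvg_vmr_side": "above",
  "hvg_top_n": 300,
  "jackstraw_iter": 30,
  "n_pcs": 12,
  "knn_k": 15,
  "resolution": 1.0,
  "seed": 0,
  "sim": {
    "n_genes": 600,
    "n_cells": 600,
    "risk_set_size": 40,
    "marker_genes_per_class": 20
  }
}
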