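{
  "n_pairs": 30,
  "h2_true": 0.8,
  "prevalence_k": 0.05,
  "ibd_mean": 0.5,
  "ibd_sd": 0.04,
  "ibd_range": [0, 1],
  "snp_freq": [0.25, 0.35, 0.3],
  "snp_beta": [1.09861228866811, 0.916290731874155, 0.693147180559945],
  "polygenic_sd": 1.3,
  "dr34_penetrance": 0.8,
  "dr34_background": 0.1,
  "ascertain_proband": true,
  "region_count": 0,
  "region_sd": 0.05,
  "seed": 2026
}
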