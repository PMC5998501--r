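{
  "sim": {
    "n_accessions": 300, "n_snps": 1000, "n_chromosomes": 5,
    "n_subpops": 2, "divergence": 0.1, "maf_min": 0.01,
    "ld_block_bp": 160000, "mean_gap_bp": 40000,
    "n_envs": 3, "n_reps": 3, "seed": 20250924
  },
  "architecture": {
    "mu": 25,
    "main": [
      {"locus": 6, "a": 1.0, "d": 0.5},
      {"locus": 401, "a": 0.5, "d": 0.0},
      {"locus": 605, "a": -0.5, "d": 0.0}
    ],
    "epistasis": [
      {"locus_i": 401, "locus_j": 605,
       "aa": 0.0, "ad": 0.0, "da": 0.0, "dd": 2.0}
    ],
    "env_sd": 1.0,
    "gxe_sds": {"ae": 0.5},
    "residual_sd": 1.0
  },
  "pipeline": {
    "n_perm": 200, "alpha": 0.05, "n_iter": 2000, "burn_in": 400,
    "seed": 77
  }
}
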