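{
  "seed": 42,
  "files": {
    "salmon_qtl_private": "map1_private.txt",
    "salmon_chr26_published": "map2_published.txt",
    "stickleback_grpIV_hits": "map3_stickleback_hits.txt",
    "medaka_chr12_hits": "map4_medaka_hits.txt",
    "stickleback_grpIV_asm": "map5_stickleback_asm.txt",
    "medaka_chr12_asm": "map6_medaka_asm.txt"
  },
  "columns": [
    "salmon_qtl_private",
    "salmon_chr26_published",
    ["stickleback_grpIV_hits", "medaka_chr12_hits"],
    ["stickleback_grpIV_asm", "medaka_chr12_asm"]
  ],
  "identity_pairs": [
    ["salmon_qtl_private", "salmon_chr26_published"],
    ["stickleback_grpIV_hits", "stickleback_grpIV_asm"],
    ["medaka_chr12_hits", "medaka_chr12_asm"]
  ],
  "synonymy_pairs": [
    ["salmon_chr26_published", "stickleback_grpIV_hits"],
    ["salmon_chr26_published", "medaka_chr12_hits"]
  ],
  "n_private_shared": 6,
  "n_bridge": [6, 6]
}
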