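{
  "maps": [
    {
      "map_id": "salmon_qtl_private",
      "x": 0,
      "y": 40,
      "width": 120,
      "height": 420
    },
    {
      "map_id": "salmon_chr26_published",
      "x": 200,
      "y": 20,
      "width": 120,
      "height": 460
    },
    {
      "map_id": "stickleback_grpIV_hits",
      "x": 400,
      "y": 10,
      "width": 120,
      "height": 220
    },
    {
      "map_id": "medaka_chr12_hits",
      "x": 460,
      "y": 260,
      "width": 120,
      "height": 220
    },
    {
      "map_id": "stickleback_grpIV_asm",
      "x": 660,
      "y": 10,
      "width": 130,
      "height": 220,
      "label_mode": "linked_only"
    },
    {
      "map_id": "medaka_chr12_asm",
      "x": 700,
      "y": 260,
      "width": 130,
      "height": 220,
      "label_mode": "linked_only"
    }
  ]
}
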