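{
  "note": "Synthetic stand-in annotation; coordinates are 1-based closed, identical for the three clade consensuses (substitution-only divergence).",
  "length_aa": 580,
  "domains": {
    "NTD": {
      "start": 1,
      "end": 117
    },
    "DDBD1": {
      "start": 118,
      "end": 263
    },
    "DDD": {
      "start": 264,
      "end": 457
    },
    "DDBD2": {
      "start": 458,
      "end": 520
    },
    "CRD": {
      "start": 521,
      "end": 580
    }
  },
  "triad_positions": [268, 346, 447],
  "insertion_motif": {
    "start": 380,
    "end": 420
  },
  "ddbd2_tryptophan": 458,
  "crd_cysteines": [524, 531, 538, 548, 555, 562, 572],
  "crd_cysteine_gaps": [7, 7, 10, 7, 7, 10]
}
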