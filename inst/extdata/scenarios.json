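{
  "n": 300,
  "lognormal": {
    "met_sp_a": {
      "relationship": "metabolite-species", "zeroInflation": "balanced_low",
      "nzero": [30, 60], "means": [14, 11],
      "mechanisms": ["rank_based", "random_exact"]
    },
    "met_sp_b": {
      "relationship": "metabolite-species", "zeroInflation": "balanced_high",
      "nzero": [150, 200], "means": [12, 9],
      "mechanisms": ["rank_based", "random_exact"]
    },
    "met_sp_c": {
      "relationship": "metabolite-species", "zeroInflation": "unbalanced_1",
      "nzero": [30, 200], "means": [14, 9],
      "mechanisms": ["rank_based", "random_exact"]
    },
    "met_sp_d": {
      "relationship": "metabolite-species", "zeroInflation": "unbalanced_2",
      "nzero": [150, 60], "means": [12, 11],
      "mechanisms": ["rank_based", "random_exact"]
    },
    "sp_sp_a": {
      "relationship": "species-species", "zeroInflation": "balanced_low",
      "nzero": [60, 60], "means": [11, 11],
      "mechanisms": ["random_exact", "random_exact"]
    },
    "sp_sp_b": {
      "relationship": "species-species", "zeroInflation": "balanced_high",
      "nzero": [200, 200], "means": [9, 9],
      "mechanisms": ["random_exact", "random_exact"]
    },
    "sp_sp_c": {
      "relationship": "species-species", "zeroInflation": "unbalanced_1",
      "nzero": [60, 200], "means": [11, 9],
      "mechanisms": ["random_exact", "random_exact"]
    }
  },
  "bzinb": {
    "bzinb_a": {
      "zeroInflation": "balanced_low",
      "pi": [0.75, 0.15, 0.05, 0.05], "expectedZeros": [30, 60]
    },
    "bzinb_b": {
      "zeroInflation": "balanced_high",
      "pi": [0.1, 0.2, 0.1, 0.6], "expectedZeros": [210, 240]
    },
    "bzinb_c": {
      "zeroInflation": "unbalanced_1",
      "pi": [0.2, 0.6, 0.05, 0.15], "expectedZeros": [60, 225]
    },
    "bzinb_d": {
      "zeroInflation": "unbalanced_2",
      "pi": [0.2, 0.05, 0.6, 0.15], "expectedZeros": [225, 60]
    }
  }
}
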