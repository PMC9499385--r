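{
  "type": "object",
  "required": ["config_hash", "seed", "stages_run", "qc", "filters"],
  "properties": {
    "config_hash": {"type": "string"},
    "seed": {"type": "number"},
    "stages_run": {"type": "array"},
    "qc": {
      "type": "object",
      "required": ["n_samples_in", "n_samples_retained", "exclusions"],
      "properties": {
        "n_samples_in": {"type": "number"},
        "n_samples_retained": {"type": "number"}
      }
    },
    "filters": {
      "type": "object",
      "required": ["n_mirnas_raw", "n_after_noise_filter", "n_expressed"],
      "properties": {
        "n_mirnas_raw": {"type": "number"},
        "n_after_noise_filter": {"type": "number"},
        "n_expressed": {"type": "number"}
      }
    },
    "profiles": {
      "type": "object",
      "required": ["diversity", "top20_fraction", "overlap_regions", "pc_variance"],
      "properties": {
        "overlap_union": {"type": "number"}
      }
    },
    "hemoscore": {
      "type": "object",
      "required": ["hemolysis_score", "seq_hemolysis_ratio", "origin_fractions"],
      "properties": {}
    },
    "diffexpr": {
      "type": "object",
      "required": ["n_contrasts", "n_significant_comparisons", "de_mirnas"],
      "properties": {
        "n_contrasts": {"type": "number"},
        "n_significant_comparisons": {"type": "number"}
      }
    },
    "qpcr": {
      "type": "object",
      "required": ["n_retained", "dcq", "rbc_platelet_ratio", "normfinder"],
      "properties": {
        "n_retained": {"type": "number"}
      }
    }
  }
}
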