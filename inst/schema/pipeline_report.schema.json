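{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "xtissue pipeline report",
  "type": "object",
  "required": ["network", "partition_sizes", "communities", "provenance"],
  "properties": {
    "network": {
      "type": "object",
      "required": ["n_nodes", "n_edges", "mean_r", "modularity", "n_communities"],
      "properties": {
        "n_nodes": {"type": "integer", "minimum": 0},
        "n_edges": {"type": "integer", "minimum": 0},
        "mean_r": {"type": "number"},
        "n_candidates": {"type": "integer"},
        "modularity": {"type": "number", "minimum": -0.5, "maximum": 1},
        "n_communities": {"type": "integer", "minimum": 0},
        "n_unassigned": {"type": "integer", "minimum": 0}
      }
    },
    "partition_sizes": {"type": "object"},
    "communities": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["community", "F_interaction", "p_interaction",
                     "fc_sm", "p_sm", "fc_sat", "p_sat", "n_subjects"]
      }
    },
    "traits": {
      "type": ["array", "null"],
      "items": {
        "type": "object",
        "required": ["community", "trait", "r", "p", "n"]
      }
    },
    "opls": {"type": ["object", "null"]},
    "truth_matching": {"type": ["array", "null"]},
    "provenance": {
      "type": "object",
      "required": ["package", "version", "seed", "config_hash"]
    }
  }
}
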