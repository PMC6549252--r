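{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "geovar pipeline report",
  "type": "object",
  "required": ["tool", "version", "seed", "inputs", "settings", "sites",
               "genetic_matrices", "mantel", "spearman", "clusters",
               "warnings"],
  "properties": {
    "tool": {"const": "geovar"},
    "version": {"type": "string"},
    "seed": {"type": "integer"},
    "inputs": {
      "type": "object",
      "additionalProperties": {
        "type": "object",
        "properties": {"path": {"type": "string"}, "md5": {"type": ["string", "null"]}}
      }
    },
    "settings": {
      "type": "object",
      "required": ["n_perm", "alternative", "thresholds", "linkage",
                   "distance_convention"]
    },
    "sites": {
      "type": "object",
      "required": ["names", "plates"]
    },
    "geographic_matrix": {"$ref": "#/$defs/labeledMatrix"},
    "genetic_matrices": {
      "type": "object",
      "additionalProperties": {"$ref": "#/$defs/labeledMatrix"}
    },
    "mantel": {
      "type": "object",
      "additionalProperties": {
        "type": ["object", "null"],
        "required": ["r_m", "n", "d", "p_value", "n_perm", "exhaustive",
                     "alternative"]
      }
    },
    "spearman": {
      "type": "object",
      "additionalProperties": {
        "type": ["object", "null"],
        "required": ["r_s", "n", "n_pairs", "p_value", "n_perm",
                     "exhaustive", "alternative"]
      }
    },
    "clusters": {
      "type": "object",
      "additionalProperties": {
        "type": "object",
        "additionalProperties": {
          "type": "object",
          "required": ["partition", "threshold", "linkage"]
        }
      }
    },
    "warnings": {"type": "array", "items": {"type": "string"}}
  },
  "$defs": {
    "labeledMatrix": {
      "type": "object",
      "required": ["labels", "kind", "values"],
      "properties": {
        "labels": {"type": "array", "items": {"type": "string"}},
        "kind": {"type": "string"},
        "values": {
          "type": "array",
          "items": {"type": "array", "items": {"type": "number"}}
        }
      }
    }
  }
}
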