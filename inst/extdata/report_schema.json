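{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "wpcna pipeline run report",
  "type": "object",
  "required": ["n_proteins_input", "n_samples", "n_proteins_network",
               "beta", "module_sizes", "n_unassigned", "seed", "parameters"],
  "properties": {
    "n_proteins_input": {"type": "integer", "minimum": 1},
    "n_samples": {"type": "integer", "minimum": 1},
    "n_proteins_network": {"type": "integer", "minimum": 1},
    "beta": {"type": "integer", "minimum": 1},
    "module_sizes": {"type": "object",
                     "additionalProperties": {"type": "integer", "minimum": 1}},
    "n_unassigned": {"type": "integer", "minimum": 0},
    "signature_module": {"type": "string", "pattern": "^M[0-9]+$"},
    "logrank_p": {"type": "number", "minimum": 0, "maximum": 1},
    "seed": {"type": "integer"},
    "parameters": {
      "type": "object",
      "required": ["top_fraction", "min_size", "n_top", "k", "iterations"],
      "properties": {
        "top_fraction": {"type": "number", "exclusiveMinimum": 0, "maximum": 1},
        "min_size": {"type": "integer", "minimum": 1},
        "n_top": {"type": "integer", "minimum": 1},
        "k": {"type": "integer", "minimum": 2},
        "iterations": {"type": "integer", "minimum": 1}
      }
    }
  }
}
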