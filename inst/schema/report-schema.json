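{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "quadscreen candidate report",
  "type": "object",
  "required": ["candidates", "trace", "denovo", "panel"],
  "properties": {
    "candidates": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["gene", "klass", "section", "sites", "rare", "consensus_ok", "passes"]
      }
    },
    "trace": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["stage", "n_in", "n_out"]
      }
    },
    "denovo": { "type": "array" },
    "panel": {
      "type": "object",
      "required": ["name", "hits"]
    },
    "susceptibility": { "type": ["array", "null"] },
    "karyotypes": { "type": ["array", "null"] }
  }
}
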