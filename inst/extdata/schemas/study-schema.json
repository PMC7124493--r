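{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "study record",
  "description": "One reviewed study's concluded causal structure",
  "type": "object",
  "required": ["study_id", "exposures", "outcomes"],
  "properties": {
    "study_id": {"type": "string"},
    "citation": {"type": "string"},
    "exposures": {"type": "array", "items": {"type": "string"}},
    "outcomes": {"type": "array", "items": {"type": "string"}},
    "controls": {"type": "array", "items": {"type": "string"}},
    "mediators": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["tail", "head"],
        "properties": {
          "tail": {"type": "string"},
          "head": {"type": "string"}
        }
      }
    },
    "instruments": {
      "type": "object",
      "additionalProperties": {"type": "string"}
    }
  },
  "additionalProperties": false
}
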