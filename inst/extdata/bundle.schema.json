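{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "Trial bundle metadata (<trial>.meta.json accompanying <trial>.tsv)",
  "type": "object",
  "required": ["fs_hz", "trial_id", "events"],
  "properties": {
    "fs_hz": { "type": "number", "exclusiveMinimum": 0,
               "description": "sampling rate in Hz" },
    "patient_id": { "type": "string" },
    "trial_id": { "type": "string" },
    "outcome": { "enum": ["success", "failure", "unknown"] },
    "n_samples": { "type": "integer" },
    "n_channels": { "type": "integer" },
    "orientation": { "const": "samples_x_channels" },
    "events": {
      "type": "array",
      "description": "strictly increasing; AD_Start, Qes_Start, AD_End mandatory",
      "items": {
        "type": "object",
        "required": ["name", "time_s"],
        "properties": {
          "name": { "enum": ["AD_Start", "Qes_Start", "Qes_End",
                             "Ans_Start", "Ans_End", "AD_End"] },
          "time_s": { "type": "number", "minimum": 0 }
        }
      }
    },
    "excluded_channels": {
      "type": "array", "items": { "type": "string" },
      "description": "artifact-dominated channel labels dropped on read"
    }
  }
}
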