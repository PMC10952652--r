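{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "capria reconstruction provenance sidecar",
  "type": "object",
  "required": ["solver", "pld_s", "window_s", "voxel_mm"],
  "properties": {
    "solver": { "enum": ["cg-sense", "llr", "quicklook"] },
    "accel": { "enum": ["pogm", "fista"] },
    "pld_s": { "type": ["array", "number"] },
    "window_s": { "type": "number" },
    "voxel_mm": { "type": "number" },
    "undersampling": { "type": ["number", "null"] },
    "config": {
      "type": "object",
      "properties": {
        "lambda_spatial": { "type": "number" },
        "lambda_temporal": { "type": "number" },
        "lambda_llr": { "type": "number" },
        "patch_size": { "type": "integer" },
        "n_iters": { "type": "integer" },
        "cycle_spinning": { "type": "boolean" },
        "seed": { "type": "integer" }
      }
    }
  }
}
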