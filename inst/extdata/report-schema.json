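{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "ctgdiag diagnosis report",
  "type": "object",
  "required": ["schema", "trace_label", "criteria", "config", "decels",
               "sustained", "alerts"],
  "properties": {
    "schema": {"const": "ctgdiag-report-v1"},
    "trace_label": {"type": "string"},
    "criteria": {
      "type": "object",
      "properties": {
        "tachy_bpm": {"type": "number"},
        "brady_bpm": {"type": "number"},
        "sustained_min_s": {"type": "number"},
        "fall_time_s": {"type": "number"},
        "uc_lag_s": {"type": "number"},
        "depth_bpm": {"type": "number"},
        "shoulder_height_bpm": {"type": "number"},
        "shoulder_lag_s": {"type": "number"},
        "patient": {"type": "string"}
      }
    },
    "config": {"type": "object"},
    "decels": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["hrs", "hrp", "hre", "cycle", "b", "labels"],
        "properties": {
          "hrs": {"$ref": "#/$defs/keypoint"},
          "hrp": {"$ref": "#/$defs/keypoint"},
          "hre": {"$ref": "#/$defs/keypoint"},
          "shoulder": {
            "type": ["object", "null"],
            "properties": {
              "hsp": {"$ref": "#/$defs/keypoint"},
              "hse": {"$ref": "#/$defs/keypoint"}
            }
          },
          "cycle": {
            "type": "object",
            "properties": {
              "ucs": {"$ref": "#/$defs/keypoint"},
              "ucp": {"$ref": "#/$defs/keypoint"},
              "uce": {"$ref": "#/$defs/keypoint"}
            }
          },
          "b": {"type": "number"},
          "labels": {"type": "array", "items": {"type": "string"}},
          "ambiguous": {"type": "boolean"}
        }
      }
    },
    "sustained": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["start", "end", "duration_s", "kind", "extreme_v",
                     "label"],
        "properties": {
          "start": {"type": "number"},
          "end": {"type": "number"},
          "duration_s": {"type": "number"},
          "kind": {"enum": ["high", "low"]},
          "extreme_v": {"type": "number"},
          "label": {"enum": ["Tachycardia", "Bradycardia"]}
        }
      }
    },
    "alerts": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["t", "label", "episode_id", "recipient"],
        "properties": {
          "t": {"type": "number"},
          "label": {"type": "string"},
          "episode_id": {"type": "string"},
          "recipient": {"type": "string"}
        }
      }
    },
    "baseline": {"type": "array"},
    "uc_tone": {"type": "array"},
    "segments": {"type": "array"}
  },
  "$defs": {
    "keypoint": {
      "type": "object",
      "required": ["t", "v"],
      "properties": {"t": {"type": "number"}, "v": {"type": "number"}}
    }
  }
}
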