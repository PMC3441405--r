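{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "uncoupleR pipeline summary report",
  "type": "object",
  "required": ["coupling_summary", "buffering", "log"],
  "properties": {
    "coupling_summary": {
      "type": "object",
      "required": ["counts", "n_degs", "uncoupled_pct", "coupled_pct"],
      "properties": {
        "counts": {
          "type": "object",
          "required": ["coupled", "antidirectional", "transcriptome_only",
                       "translatome_only", "unchanged"],
          "additionalProperties": {"type": "integer", "minimum": 0}
        },
        "n_degs": {"type": "integer", "minimum": 0},
        "uncoupled_pct": {"type": ["number", "null"]},
        "coupled_pct": {"type": ["number", "null"]},
        "translatome_to_transcriptome_ratio": {"type": ["number", "null"]}
      }
    },
    "buffering": {
      "type": "object",
      "required": ["n_enhanced", "n_buffered", "n_tied"],
      "properties": {
        "n_enhanced": {"type": "integer", "minimum": 0},
        "n_buffered": {"type": "integer", "minimum": 0},
        "n_tied": {"type": "integer", "minimum": 0},
        "enhanced_pct": {"type": ["number", "null"]},
        "buffered_pct": {"type": ["number", "null"]}
      }
    },
    "term_overlap": {
      "type": "object",
      "properties": {
        "n_common": {"type": "integer", "minimum": 0},
        "n_transcriptome_only": {"type": "integer", "minimum": 0},
        "n_translatome_only": {"type": "integer", "minimum": 0}
      }
    },
    "specificity": {
      "type": "object",
      "properties": {
        "m": {"type": "integer", "minimum": 0},
        "n": {"type": "integer", "minimum": 0},
        "translatome_specificity": {"type": ["number", "null"]},
        "transcriptome_specificity": {"type": ["number", "null"]}
      }
    },
    "independence": {
      "type": "object",
      "required": ["N", "n1", "n2", "k", "lrt_stat", "lrt_p", "overlap_p",
                   "overlap_p_exact", "mi_observed", "mi_min", "mi_max",
                   "mi_p"],
      "properties": {
        "N": {"type": "integer", "minimum": 1},
        "n1": {"type": "integer", "minimum": 0},
        "n2": {"type": "integer", "minimum": 0},
        "k": {"type": "integer", "minimum": 0},
        "lrt_p": {"type": "number", "minimum": 0, "maximum": 1},
        "overlap_p": {"type": "number", "exclusiveMinimum": 0, "maximum": 1},
        "mi_p": {"type": "number", "exclusiveMinimum": 0, "maximum": 1},
        "mi_observed": {"type": "number", "minimum": 0},
        "mi_midrange_position": {"type": ["number", "null"]}
      }
    },
    "log": {"type": "array", "items": {"type": "string"}}
  }
}
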