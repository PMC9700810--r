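{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "maxcaliber run summary",
  "type": "object",
  "required": ["config", "n_states", "training_loss", "unconstrained", "wall_time_s"],
  "properties": {
    "config": {"type": "object"},
    "n_states": {"type": "integer", "minimum": 2},
    "training_loss": {"type": "array", "items": {"type": "number"}},
    "unconstrained": {
      "type": "object",
      "properties": {
        "nn_rate": {"type": "object"},
        "kernel": {"type": ["array", "null"]},
        "eigenvalues": {"type": ["array", "null"]}
      }
    },
    "constrained": {
      "type": "object",
      "required": ["delta_lambda", "achieved_model", "targets", "ess"],
      "properties": {
        "delta_lambda": {"type": ["number", "array"]},
        "achieved_reweighted": {"type": ["number", "array"]},
        "achieved_model": {"type": ["number", "array"]},
        "targets": {"type": ["number", "array"]},
        "error_percentage": {"type": ["number", "array"]},
        "ess": {"type": "number"}
      }
    },
    "wall_time_s": {"type": "number"}
  }
}
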