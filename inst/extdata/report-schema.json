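{
  "version": "1.0",
  "required": {
    "discovery": ["schema_version", "parameters", "stages",
                  "n_candidate_variants", "n_candidate_genes"],
    "followup": ["schema_version"]
  }
}
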