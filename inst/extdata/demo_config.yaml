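# Demo configuration for `tnmstager end-to-end --config demo_config.yaml`.
# Small problem size so the demo finishes in seconds.
n: 150
seed: 7
dim: 50
n_search: 10
p_negation_sentence: 0.10
p_historical: 0.05
p_hypothetical: 0.05
p_ambiguous_prefix: 0.10
p_compact_pattern: 0.5
p_missing_documentation: 0.15
p_registry_missing: 0.25
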