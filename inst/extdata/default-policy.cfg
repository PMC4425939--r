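# aggregation policy: defaults reproduce the published worked examples
promote_count=3
multitype_promotion=true
weak_conflict_demotion=false
legacy_default_level=medium
# evidence typing over the ECO: subsumption or exact
type_mode=subsumption
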