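format-version: 1.2
ontology: toy-eco

[Term]
id: TOYECO:0000001
name: evidence

[Term]
id: TOYECO:0000002
name: experimental evidence
is_a: TOYECO:0000001 ! evidence

[Term]
id: ECO:0000015
name: mutant phenotype evidence
is_a: TOYECO:0000002 ! experimental evidence

[Term]
id: ECO:0000058
name: microarray evidence
is_a: TOYECO:0000002 ! experimental evidence

[Term]
id: TOYECO:0000003
name: similarity evidence
is_a: TOYECO:0000001 ! evidence

[Term]
id: ECO:0000200
name: sequence alignment evidence
is_a: TOYECO:0000003 ! similarity evidence

[Term]
id: ECO:0000208
name: protein BLAST evidence
is_a: TOYECO:0000003 ! similarity evidence

[Term]
id: TOYECO:0000004
name: developmental similarity evidence
is_a: TOYECO:0000003 ! similarity evidence

[Term]
id: TOYECO:0000005
name: author statement evidence
is_a: TOYECO:0000001 ! evidence

[Term]
id: ECO:0000033
name: traceable author statement
is_a: TOYECO:0000005 ! author statement evidence

[Term]
id: TOYECO:0000006
name: non-traceable author statement
is_a: TOYECO:0000005 ! author statement evidence

[Term]
id: TOYECO:0000007
name: phylogenetic distribution evidence
is_a: TOYECO:0000001 ! evidence

[Term]
id: ECO:0000501
name: automatic assertion
is_a: TOYECO:0000001 ! evidence
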