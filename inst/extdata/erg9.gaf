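!gaf-version: 2.0
! Candida glabrata ERG9 / squalene synthase activity, two high-confidence lines
! (synthetic reference id: the source publication's PMID is not recorded here)
UniProtKB	Q9HGZ6	ERG9		GO:0051996	REF:ERG9-SOURCE	ISA		F	squalene synthase	ERG9	protein	taxon:5478	20150203	UniProt			high confidence from single evidence
UniProtKB	Q9HGZ6	ERG9		GO:0051996	REF:ERG9-SOURCE	IMP		F	squalene synthase	ERG9	protein	taxon:5478	20150203	UniProt			high confidence from single evidence
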