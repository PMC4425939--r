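Entity name	Qualifier	Taxon name	Line type	Evidence term name	Confidence term name	Reference ID
Autopod	—	Vertebrata	RAW	Traceable author statement	Medium confidence from single evidence	PMID:23598338
Autopod	NOT	Vertebrata	RAW	Traceable author statement	Medium confidence from single evidence	PMID:23598338
Autopod	—	Vertebrata	SUMMARY		Confidence statement from strongly conflicting evidence lines of same type	—
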