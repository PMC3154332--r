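# Transcription of published Table 2: in silico vs PCR product polymorphism over 38 interpretable loci
insilico	pcr_polymorphic	pcr_monomorphic
polymorphic	22	8
monomorphic	1	7
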