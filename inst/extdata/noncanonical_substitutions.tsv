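code	canonical	delete_atoms
SEP	SER	P,O1P,O2P,O3P
TPO	THR	P,O1P,O2P,O3P
PTR	TYR	P,O1P,O2P,O3P
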