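foreign_id	reaction_ids
KEGG:R00086	RHEA:13065
EC:2.7.2.1	RHEA:11352
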