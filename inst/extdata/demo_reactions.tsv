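reaction_id	participants
RHEA:13065	CHEBI:30616|CHEBI:15377|CHEBI:456216|CHEBI:15378|CHEBI:43474
RHEA:11352	CHEBI:30089|CHEBI:30616|CHEBI:22191|CHEBI:456216|CHEBI:15378
RHEA:50112	CHEBI:17634|CHEBI:15377
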