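term_id	name	synonyms	formula
CHEBI:30616	ATP	ATP|adenosine 5'-triphosphate|adenosine triphosphate	C10H16N5O13P3
CHEBI:456216	ADP	ADP|adenosine 5'-diphosphate|adenosine diphosphate	C10H15N5O10P2
CHEBI:16027	AMP	AMP|adenosine 5'-monophosphate|adenosine monophosphate	C10H14N5O7P
CHEBI:15377	water	water|H2O	H2O
CHEBI:15378	hydron	hydron|H(+)|proton	H+
CHEBI:43474	hydrogenphosphate	hydrogenphosphate|phosphate|HPO4(2-)	HPO4
CHEBI:30089	acetate	acetate|acetic acid, ion(1-)	C2H3O2
CHEBI:22191	acetyl phosphate	acetyl phosphate|acetylphosphate	C2H5O5P
CHEBI:17634	D-glucose	D-glucose|dextrose|grape sugar	C6H12O6
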