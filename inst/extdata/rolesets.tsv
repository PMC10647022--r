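lemma	sense	origin_type	arg0	arg1	arg2
add	01	A		thing being added	thing being added to
stir	01	A		thing stirred
charge	01	C		vessel being charged	material charged into the vessel
cool	01	C		thing cooled	instrument used for cooling
heat	01	A		thing heated	instrument used for heating
remove	01	A		thing removed	place removed from
backfill	01	D		vessel backfilled	gas used for backfilling
place	01	A		thing placed	location
reflux	01	D		thing refluxed
transfer	01	A		thing transferred	destination
dissolve	01	A		thing dissolved	solvent
fill	01	A		vessel filled	substance
wrap	01	A		thing wrapped	covering
wash	01	A		thing washed	washing liquid
hold	01	C		thing held
mix	01	B		ingredient
open	01	A		thing opened
activate	01	C		thing activated
contain	01	A	container	thing contained
keep	01	A		thing kept
maintain	01	A		thing maintained
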