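surface	lemma
addition	add
held	hold
kept	keep
stirring	stir
mixing	mix
dissolution	dissolve
refluxing	reflux
transferal	transfer
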