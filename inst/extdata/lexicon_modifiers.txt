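dropwise
in one portion
portionwise
under nitrogen
under argon
under vacuum
with vigorous stirring
stirring
slowly
vigorously
via cannula
in the dark
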