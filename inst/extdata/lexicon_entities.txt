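DMF
anhydrous CH2Cl2
dichloromethane
THF
anhydrous THF
toluene
methanol
ethanol
diethyl ether
ethyl acetate
benzaldehyde
triethylamine
12-aminododecanolactam
sodium chloride
sodium hydride
potassium carbonate
acetic anhydride
n-butyllithium
ammonium chloride
cyclohexanone
pyridine
acetonitrile
a 500-mL three-necked round-bottomed flask
a 250-mL round-bottomed flask
a 1-L round-bottomed flask
a 100-mL Schlenk flask
the flask
the reaction vessel
a dropping funnel
an oil bath
the cooling bath
aluminum foil
dry nitrogen gas
dry argon gas
The mixture
the mixture
The reaction mixture
the reaction mixture
The resulting solution
the resulting solution
The suspension
the suspension
The solution
the solution
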