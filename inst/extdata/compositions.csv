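# Solvent compositions by molar ratio (nominal, as weighed in).
# Glucose enters anhydrous, with recipe water as an explicit component.
# molar_mass: standard average atomic masses, g/mol; PEG300 nominal.
label,component,molar_mass,ratio
CU,choline chloride,139.62,1
CU,urea,60.06,2
CG,choline chloride,139.62,1
CG,glycerol,92.09,2
CLW,choline chloride,139.62,1
CLW,lactic acid,90.08,0.9
CLW,water,18.015,0.6
BGW,betaine,117.15,1
BGW,glycerol,92.09,2
BGW,water,18.015,1
CGW,choline chloride,139.62,1
CGW,glucose,180.16,0.4
CGW,water,18.015,1
LGW,lactic acid,90.08,1
LGW,glucose,180.16,0.2
LGW,water,18.015,1.2
Ethanol,ethanol,46.07,1
Glycerol,glycerol,92.09,1
PEG300,PEG 300,300.0,1
Water,water,18.015,1
LacticAcid,lactic acid,90.08,1
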