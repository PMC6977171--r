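# Solute metadata: standard average molar masses, g/mol.
api,molar_mass
Naproxen,230.26
Paracetamol,151.16
Ibuprofen,206.28
Flufenamic acid,281.23
Indomethacin,357.79
Lidocaine,234.34
Theophylline,180.16
Celecoxib,381.37
Aprepitant,534.43
Probucol,516.84
Cinnarizine,368.51
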