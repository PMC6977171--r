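# Measured solubility (mg API per g solvent, mean +/- SD, n = 3)
# after 24 h agitation at room temperature.
# flag: below_LOQ = below limit of quantification (no mean);
#       phase_separation = solvent demixed on dissolution (no mean);
#       viscous = medium too viscous to stir (value retained).
api,solvent,mean_mg_per_g,sd_mg_per_g,n,flag
Naproxen,CU,9.5,0.1,3,
Naproxen,CG,4.4,0.1,3,
Naproxen,CLW,14.2,0.1,3,
Naproxen,BGW,4.6,0.2,3,
Naproxen,LGW,1.85,0.08,3,
Naproxen,CGW,2.89,0.06,3,
Naproxen,Ethanol,110,6,3,
Naproxen,Glycerol,1.25,0.05,3,
Naproxen,PEG300,412,11,3,
Naproxen,Water,0.0452,0.0005,3,
Paracetamol,CU,123,4,3,
Paracetamol,CG,94.8,0.8,3,
Paracetamol,CLW,200.5,6,3,
Paracetamol,BGW,80,6,3,
Paracetamol,LGW,26.2,2,3,
Paracetamol,CGW,54.0,2,3,
Paracetamol,Ethanol,155,3,3,
Paracetamol,Glycerol,20.9,0.3,3,
Paracetamol,PEG300,102,1,3,
Paracetamol,Water,7.9,0.2,3,
Ibuprofen,CU,9,2,3,
Ibuprofen,CG,4.5,0.8,3,
Ibuprofen,CLW,14.0,0.5,3,
Ibuprofen,BGW,4.9,0.2,3,
Ibuprofen,LGW,6.1,0.2,3,
Ibuprofen,CGW,1.30,0.14,3,
Ibuprofen,Ethanol,67,18,3,
Ibuprofen,Glycerol,2.3,0.1,3,
Ibuprofen,PEG300,304,9,3,
Ibuprofen,Water,0.055,0.004,3,
Flufenamic acid,CU,2.19,0.05,3,
Flufenamic acid,CG,1.05,0.05,3,
Flufenamic acid,CLW,5.02,0.06,3,
Flufenamic acid,BGW,11.8,1.0,3,
Flufenamic acid,LGW,0.085,0.003,3,
Flufenamic acid,CGW,0.176,0.006,3,
Flufenamic acid,Ethanol,266,6,3,
Flufenamic acid,Glycerol,0.45,0.06,3,
Flufenamic acid,PEG300,303,15,3,
Flufenamic acid,Water,0.0029,0.0001,3,
Indomethacin,CU,8.4,0.1,3,
Indomethacin,CG,5.0,0.2,3,
Indomethacin,CLW,15.9,0.9,3,
Indomethacin,BGW,23.0,0.6,3,
Indomethacin,LGW,5.06,0.05,3,
Indomethacin,CGW,0.95,0.00,3,
Indomethacin,Ethanol,160,8,3,
Indomethacin,Glycerol,1.34,0.08,3,
Indomethacin,PEG300,632,23,3,
Indomethacin,Water,0.055,0.004,3,
Lidocaine,CU,1.36,0.06,3,
Lidocaine,CG,5.77,0.07,3,
Lidocaine,CLW,134.7,2,3,
Lidocaine,BGW,3.48,0.02,3,
Lidocaine,LGW,459,15,3,viscous
Lidocaine,CGW,1.2,0.1,3,
Lidocaine,Ethanol,20.5,0.7,3,
Lidocaine,Glycerol,10.6,0.2,3,
Lidocaine,PEG300,307,3,3,
Lidocaine,Water,3.80,0.05,3,
Theophylline,CU,2.2,0.2,3,
Theophylline,CG,0.28,0.03,3,
Theophylline,CLW,4.1,0.1,3,
Theophylline,BGW,3.42,0.04,3,
Theophylline,LGW,63.5,0.5,3,
Theophylline,CGW,1.08,0.03,3,
Theophylline,Ethanol,0.81,0.02,3,
Theophylline,Glycerol,1.66,0.07,3,
Theophylline,PEG300,1.23,0.09,3,
Theophylline,Water,6.4,0.1,3,
Celecoxib,CU,1.78,0.03,3,
Celecoxib,CG,3.86,0.02,3,
Celecoxib,CLW,18.6,0.0,3,
Celecoxib,BGW,3.25,0.04,3,
Celecoxib,LGW,1.81,0.00,3,
Celecoxib,CGW,0.40,0.02,3,
Celecoxib,Ethanol,100,5,3,
Celecoxib,Glycerol,0.33,0.03,3,
Celecoxib,PEG300,395,36,3,
Celecoxib,Water,0.00148,0.00007,3,
Aprepitant,CU,0.0133,0.0003,3,
Aprepitant,CG,0.0038,0.009,3,
Aprepitant,CLW,2.03,0.3,3,
Aprepitant,BGW,0.058,0.009,3,
Aprepitant,LGW,7.2,0.1,3,
Aprepitant,CGW,0.031,0.02,3,
Aprepitant,Ethanol,4.9,0.3,3,
Aprepitant,Glycerol,0.973,0.06,3,
Aprepitant,PEG300,1.0,0.2,3,
Aprepitant,Water,NA,NA,3,below_LOQ
Probucol,CU,0.0318,0.001,3,
Probucol,CG,0.02,0.01,3,
Probucol,CLW,0.03,0.01,3,
Probucol,BGW,0.067,0.009,3,
Probucol,LGW,0.010,0.004,3,
Probucol,CGW,0.034,0.03,3,
Probucol,Ethanol,36,2,3,
Probucol,Glycerol,0.3,0.2,3,
Probucol,PEG300,19.0,0.2,3,
Probucol,Water,NA,NA,3,below_LOQ
Cinnarizine,CU,0.013,0.004,3,
Cinnarizine,CG,0.06,0.02,3,
Cinnarizine,CLW,2.8,0.5,3,
Cinnarizine,BGW,0.04,0.03,3,
Cinnarizine,LGW,NA,NA,3,phase_separation
Cinnarizine,CGW,0.038,0.03,3,
Cinnarizine,Ethanol,9.5,0.5,3,
Cinnarizine,Glycerol,0.03,0.01,3,
Cinnarizine,PEG300,12.4,0.3,3,
Cinnarizine,Water,0.0006,0.0001,3,
Paracetamol,LacticAcid,96.5,5.5,3,
Theophylline,LacticAcid,116.4,2.7,3,
Aprepitant,LacticAcid,83.5,22.8,3,
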