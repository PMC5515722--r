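# alphadose embedded decay data, v1 (2026-09)
# Intensity-weighted mean alpha energy (MeV) and alpha yield per parent decay
# for each member of the local decay chain, assuming secular equilibrium.
# Values compiled from standard evaluated decay data (ENSDF/NNDC). Rows with
# yield = 0 are non-alpha members kept only to carry member half-lives.
# Parent half-lives for Ac-225 / Pb-212 / At-211 use the rounded conventional
# values 240 h (10 d), 10.6 h and 7.2 h.
nuclide,member,mean_energy_MeV,yield,half_life_h
Ac-225,Ac-225,5.790,1.0000,240.0
Ac-225,Fr-221,6.301,0.9990,0.0800
Ac-225,At-217,7.066,0.9999,8.97e-6
Ac-225,Bi-213,5.870,0.0216,0.76017
Ac-225,Po-213,8.376,0.9784,1.03e-9
Ac-225,Tl-209,0,0,0.0362
Bi-213,Bi-213,5.870,0.0216,0.76017
Bi-213,Po-213,8.376,0.9784,1.03e-9
Bi-213,Tl-209,0,0,0.0362
Pb-212,Pb-212,0,0,10.6
Pb-212,Bi-212,6.062,0.3594,1.0092
Pb-212,Po-212,8.785,0.6406,8.3e-11
Pb-212,Tl-208,0,0,0.0509
At-211,At-211,5.867,0.4180,7.2
At-211,Po-211,7.450,0.5820,1.43e-7
At-211,Bi-207,0,0,2.76e5
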