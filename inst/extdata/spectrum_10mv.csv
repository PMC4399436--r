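# Representative 10 MV photon fluence spectrum (literature-style fixture,
# not machine-specific). Mean energy ~2.7 MeV.
energy_MeV,weight
0.25,0.012
0.50,0.055
0.75,0.085
1.00,0.100
1.50,0.115
2.00,0.110
2.50,0.100
3.00,0.090
3.50,0.075
4.00,0.062
5.00,0.072
6.00,0.048
7.00,0.032
8.00,0.022
9.00,0.014
10.00,0.008
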