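# Representative 6 MV photon fluence spectrum (literature-style fixture,
# not machine-specific). Mean energy ~1.7 MeV.
energy_MeV,weight
0.25,0.020
0.50,0.090
0.75,0.125
1.00,0.135
1.25,0.125
1.50,0.110
1.75,0.095
2.00,0.080
2.50,0.075
3.00,0.055
3.50,0.035
4.00,0.023
4.50,0.014
5.00,0.010
5.50,0.005
6.00,0.003
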