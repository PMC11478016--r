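energy_keV,muen_rho
1,4944
1.5,1464.88888888889
2,618
3,183.111111111111
4,77.25
5,39.552
6,22.8888888888889
8,9.65625
10,4.944
15,1.374
20,0.5503
30,0.1557
40,0.06947
50,0.04223
60,0.0319
80,0.02597
100,0.02546
150,0.02764
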