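element,Z,A,energy_keV,mu_rho
H,1,1.008,1,3.15761396626132
H,1,1.008,1.5,1.21341226703029
H,1,1.008,2,0.739575480463741
H,1,1.008,3,0.495129556312237
H,1,1.008,4,0.434493899086911
H,1,1.008,5,0.411949114631719
H,1,1.008,6,0.401169129130002
H,1,1.008,8,0.390876683455683
H,1,1.008,10,0.3854
H,1,1.008,15,0.3764
H,1,1.008,20,0.3695
H,1,1.008,30,0.357
H,1,1.008,40,0.3458
H,1,1.008,50,0.3355
H,1,1.008,60,0.326
H,1,1.008,80,0.3091
H,1,1.008,100,0.2944
H,1,1.008,150,0.2651
C,6,12.011,1,2180.52627168995
C,6,12.011,1.5,646.221752805475
C,6,12.011,2,272.739441137777
C,6,12.011,3,80.9506608942654
C,6,12.011,4,34.2646639311196
C,6,12.011,5,17.6389225414447
C,6,12.011,6,10.2896720879639
C,6,12.011,8,4.45255637360877
C,6,12.011,10,2.373
C,6,12.011,15,0.8071
C,6,12.011,20,0.442
C,6,12.011,30,0.2562
C,6,12.011,40,0.2076
C,6,12.011,50,0.1871
C,6,12.011,60,0.1753
C,6,12.011,80,0.161
C,6,12.011,100,0.1514
C,6,12.011,150,0.1347
N,7,14.007,1,3686.4461143818
N,7,14.007,1.5,1092.42028297443
N,7,14.007,2,460.979493795256
N,7,14.007,3,136.725549188454
N,7,14.007,4,57.794742241519
N,7,14.007,5,29.6863623725881
N,7,14.007,6,17.2616042722787
N,7,14.007,8,7.39388674102865
N,7,14.007,10,3.879
N,7,14.007,15,1.236
N,7,14.007,20,0.6178
N,7,14.007,30,0.3066
N,7,14.007,40,0.2288
N,7,14.007,50,0.198
N,7,14.007,60,0.1817
N,7,14.007,80,0.1639
N,7,14.007,100,0.1529
N,7,14.007,150,0.1353
O,8,15.999,1,5759.33779605125
O,8,15.999,1.5,1706.61048960485
O,8,15.999,2,720.091051732887
O,8,15.999,3,213.499422343611
O,8,15.999,4,90.1837839116343
O,8,15.999,5,46.2696054041121
O,8,15.999,6,26.8584345599082
O,8,15.999,8,11.4426123242319
O,8,15.999,10,5.952
O,8,15.999,15,1.836
O,8,15.999,20,0.8651
O,8,15.999,30,0.3779
O,8,15.999,40,0.2585
O,8,15.999,50,0.2132
O,8,15.999,60,0.1907
O,8,15.999,80,0.1678
O,8,15.999,100,0.1551
O,8,15.999,150,0.1361
Na,11,22.99,1,15245.6457774536
Na,11,22.99,1.5,4517.36237158
Na,11,22.99,2,1905.87205362886
Na,11,22.99,3,564.83594269014
Na,11,22.99,4,238.398974808746
Na,11,22.99,5,122.15166464476
Na,11,22.99,6,70.7681254477831
Na,11,22.99,8,29.9621959973317
Na,11,22.99,10,15.43
Na,11,22.99,15,4.694
Na,11,22.99,20,2.057
Na,11,22.99,30,0.7197
Na,11,22.99,40,0.3969
Na,11,22.99,50,0.2804
Na,11,22.99,60,0.2268
Na,11,22.99,80,0.1796
Na,11,22.99,100,0.1585
Na,11,22.99,150,0.1335
Mg,12,24.305,1,20799.7673770227
Mg,12,24.305,1.5,6163.03230327415
Mg,12,24.305,2,2600.14255729322
Mg,12,24.305,3,770.549966021403
Mg,12,24.305,4,325.188048012893
Mg,12,24.305,5,166.590584212737
Mg,12,24.305,6,96.4875960261504
Mg,12,24.305,8,40.8160060875059
Mg,12,24.305,10,20.99
Mg,12,24.305,15,6.358
Mg,12,24.305,20,2.763
Mg,12,24.305,30,0.9306
Mg,12,24.305,40,0.4881
Mg,12,24.305,50,0.3292
Mg,12,24.305,60,0.257
Mg,12,24.305,80,0.1944
Mg,12,24.305,100,0.1686
Mg,12,24.305,150,0.1394
Al,13,26.982,1,26044.3612694913
Al,13,26.982,1.5,7716.98271023944
Al,13,26.982,2,3255.7126490659
Al,13,26.982,3,964.789639180661
Al,13,26.982,4,407.130198671471
Al,13,26.982,5,208.542688028987
Al,13,26.982,6,120.763477636997
Al,13,26.982,8,51.054729991198
Al,13,26.982,10,26.23
Al,13,26.982,15,7.955
Al,13,26.982,20,3.441
Al,13,26.982,30,1.128
Al,13,26.982,40,0.5685
Al,13,26.982,50,0.3681
Al,13,26.982,60,0.2778
Al,13,26.982,80,0.2018
Al,13,26.982,100,0.1704
Al,13,26.982,150,0.1378
P,15,30.974,1,40333.4078621802
P,15,30.974,1.5,11950.7749862177
P,15,30.974,2,5041.84433335264
P,15,30.974,3,1494.01453033496
P,15,30.974,4,630.397512357274
P,15,30.974,5,322.85602526678
P,15,30.974,6,186.917435274598
P,15,30.974,8,78.9639836783706
P,15,30.974,10,40.52
P,15,30.974,15,12.45
P,15,30.974,20,5.358
P,15,30.974,30,1.7
P,15,30.974,40,0.8096
P,15,30.974,50,0.5033
P,15,30.974,60,0.3604
P,15,30.974,80,0.2435
P,15,30.974,100,0.1992
P,15,30.974,150,0.1516
S,16,32.06,1,49927.7103804756
S,16,32.06,1.5,14793.5354290014
S,16,32.06,2,6241.13728862598
S,16,32.06,3,1849.36470499304
S,16,32.06,4,780.314230118667
S,16,32.06,5,399.616209161596
S,16,32.06,6,231.341264185548
S,16,32.06,8,97.7085900390135
S,16,32.06,10,50.12
S,16,32.06,15,15.47
S,16,32.06,20,6.708
S,16,32.06,30,2.113
S,16,32.06,40,0.9872
S,16,32.06,50,0.5984
S,16,32.06,60,0.4166
S,16,32.06,80,0.2704
S,16,32.06,100,0.2149
S,16,32.06,150,0.1585
Cl,17,35.45,1,57115.2297453576
Cl,17,35.45,1.5,16923.1653311189
Cl,17,35.45,2,7139.57042497696
Cl,17,35.45,3,2115.5616864463
Cl,17,35.45,4,892.611643510712
Cl,17,35.45,5,457.108757258909
Cl,17,35.45,6,264.609212686949
Cl,17,35.45,8,111.73914590191
Cl,17,35.45,10,57.3
Cl,17,35.45,15,17.84
Cl,17,35.45,20,7.739
Cl,17,35.45,30,2.426
Cl,17,35.45,40,1.117
Cl,17,35.45,50,0.6618
Cl,17,35.45,60,0.4505
Cl,17,35.45,80,0.2815
Cl,17,35.45,100,0.219
Cl,17,35.45,150,0.1566
K,19,39.098,1,78912.760085495
K,19,39.098,1.5,23381.6946343158
K,19,39.098,2,9864.26394571594
K,19,39.098,3,2922.88006838854
K,19,39.098,4,1233.20054356119
K,19,39.098,5,631.491498364198
K,19,39.098,6,365.526202497191
K,19,39.098,8,154.314932947121
K,19,39.098,10,79.1
K,19,39.098,15,24.77
K,19,39.098,20,10.79
K,19,39.098,30,3.382
K,19,39.098,40,1.541
K,19,39.098,50,0.8887
K,19,39.098,60,0.5863
K,19,39.098,80,0.3418
K,19,39.098,100,0.2541
K,19,39.098,150,0.1678
Ca,20,40.078,1,93217.7247741294
Ca,20,40.078,1.5,27620.2063499927
Ca,20,40.078,2,11652.3890748462
Ca,20,40.078,3,3452.69855718395
Ca,20,40.078,4,1456.72069051613
Ca,20,40.078,5,745.936309749762
Ca,20,40.078,6,431.75798293362
Ca,20,40.078,8,182.259384915065
Ca,20,40.078,10,93.41
Ca,20,40.078,15,29.32
Ca,20,40.078,20,12.81
Ca,20,40.078,30,4.023
Ca,20,40.078,40,1.83
Ca,20,40.078,50,1.048
Ca,20,40.078,60,0.6837
Ca,20,40.078,80,0.3877
Ca,20,40.078,100,0.281
Ca,20,40.078,150,0.1768
Au,79,196.967,1,44986.1102725452
Au,79,196.967,1.5,15676.2135100806
Au,79,196.967,2,7419.94104744064
Au,79,196.967,3,2585.61096718954
Au,79,196.967,4,1223.83386369581
Au,79,196.967,5,685.1038880627
Au,79,196.967,6,426.466765673469
Au,79,196.967,8,201.857308077296
Au,79,196.967,10,113
Au,79,196.967,15,164
Au,79,196.967,20,77.5
Au,79,196.967,30,27.2
Au,79,196.967,40,13.09
Au,79,196.967,50,7.256
Au,79,196.967,60,4.528
Au,79,196.967,70,3.034
Au,79,196.967,80,2.137
Au,79,196.967,80.724,2.066
Au,79,196.967,80.726,8.904
Au,79,196.967,90,6.661
Au,79,196.967,100,5.158
Au,79,196.967,120,3.24
Au,79,196.967,150,1.856
Pb,82,207.2,1,51992.7964742867
Pb,82,207.2,1.5,18117.818446164
Pb,82,207.2,2,8575.6132813783
Pb,82,207.2,3,2988.32559570756
Pb,82,207.2,4,1414.44869556347
Pb,82,207.2,5,791.810334345032
Pb,82,207.2,6,492.889907937655
Pb,82,207.2,8,233.2970303973
Pb,82,207.2,10,130.6
Pb,82,207.2,15,111.6
Pb,82,207.2,20,86.36
Pb,82,207.2,30,30.32
Pb,82,207.2,40,14.36
Pb,82,207.2,50,8.041
Pb,82,207.2,60,5.021
Pb,82,207.2,70,3.518
Pb,82,207.2,80,2.419
Pb,82,207.2,88.004,1.91
Pb,82,207.2,88.006,7.683
Pb,82,207.2,100,5.549
Pb,82,207.2,120,3.5
Pb,82,207.2,150,2.014
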