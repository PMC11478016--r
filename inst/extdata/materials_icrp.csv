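material,density,element,mass_fraction
soft_tissue,1.06,H,0.102
soft_tissue,1.06,C,0.143
soft_tissue,1.06,N,0.034
soft_tissue,1.06,O,0.708
soft_tissue,1.06,Na,0.002
soft_tissue,1.06,P,0.003
soft_tissue,1.06,S,0.003
soft_tissue,1.06,Cl,0.002
soft_tissue,1.06,K,0.003
water,1,H,0.1119
water,1,O,0.8881
cortical_bone,1.92,H,0.034
cortical_bone,1.92,C,0.155
cortical_bone,1.92,N,0.042
cortical_bone,1.92,O,0.435
cortical_bone,1.92,Na,0.001
cortical_bone,1.92,Mg,0.002
cortical_bone,1.92,P,0.103
cortical_bone,1.92,S,0.003
cortical_bone,1.92,Ca,0.225
skeletal_muscle,1.05,H,0.102
skeletal_muscle,1.05,C,0.143
skeletal_muscle,1.05,N,0.034
skeletal_muscle,1.05,O,0.71
skeletal_muscle,1.05,Na,0.001
skeletal_muscle,1.05,P,0.002
skeletal_muscle,1.05,S,0.003
skeletal_muscle,1.05,Cl,0.001
skeletal_muscle,1.05,K,0.004
adipose,0.95,H,0.114
adipose,0.95,C,0.598
adipose,0.95,N,0.007
adipose,0.95,O,0.278
adipose,0.95,Na,0.001
adipose,0.95,S,0.001
adipose,0.95,Cl,0.001
brain,1.04,H,0.107
brain,1.04,C,0.145
brain,1.04,N,0.022
brain,1.04,O,0.712
brain,1.04,Na,0.002
brain,1.04,P,0.004
brain,1.04,S,0.002
brain,1.04,Cl,0.003
brain,1.04,K,0.003
lung_inflated,0.26,H,0.103
lung_inflated,0.26,C,0.105
lung_inflated,0.26,N,0.031
lung_inflated,0.26,O,0.749
lung_inflated,0.26,Na,0.002
lung_inflated,0.26,P,0.002
lung_inflated,0.26,S,0.003
lung_inflated,0.26,Cl,0.003
lung_inflated,0.26,K,0.002
gold,19.32,Au,1
lead,11.35,Pb,1
aluminum,2.699,Al,1
air,0.0012,N,0.767
air,0.0012,O,0.233
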