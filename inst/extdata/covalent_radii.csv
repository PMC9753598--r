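symbol,z,radius
H,1,0.31
He,2,0.28
Li,3,1.28
Be,4,0.96
B,5,0.84
C,6,0.76
N,7,0.71
O,8,0.66
F,9,0.57
Ne,10,0.58
Na,11,1.66
Mg,12,1.41
Al,13,1.21
Si,14,1.11
P,15,1.07
S,16,1.05
Cl,17,1.02
Ar,18,1.06
K,19,2.03
Ca,20,1.76
Sc,21,1.70
Ti,22,1.60
V,23,1.53
Cr,24,1.39
Mn,25,1.39
Fe,26,1.32
Co,27,1.26
Ni,28,1.24
Cu,29,1.32
Zn,30,1.22
Ga,31,1.22
Ge,32,1.20
As,33,1.19
Se,34,1.20
Br,35,1.20
Kr,36,1.16
Rb,37,2.20
Sr,38,1.95
Y,39,1.90
Zr,40,1.75
Nb,41,1.64
Mo,42,1.54
Tc,43,1.47
Ru,44,1.46
Rh,45,1.42
Pd,46,1.39
Ag,47,1.45
Cd,48,1.44
In,49,1.42
Sn,50,1.39
Sb,51,1.39
Te,52,1.38
I,53,1.39
Xe,54,1.40
Cs,55,2.44
Ba,56,2.15
La,57,2.07
Ce,58,2.04
Pr,59,2.03
Nd,60,2.01
Pm,61,1.99
Sm,62,1.98
Eu,63,1.98
Gd,64,1.96
Tb,65,1.94
Dy,66,1.92
Ho,67,1.92
Er,68,1.89
Tm,69,1.90
Yb,70,1.87
Lu,71,1.87
Hf,72,1.75
Ta,73,1.70
W,74,1.62
Re,75,1.51
Os,76,1.44
Ir,77,1.41
Pt,78,1.36
Au,79,1.36
Hg,80,1.32
Tl,81,1.45
Pb,82,1.46
Bi,83,1.48
Po,84,1.40
At,85,1.50
Rn,86,1.50
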