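name,row,col
Fp1,1,4
Fp2,1,6
AF3,2,4
AF4,2,6
F7,3,1
F3,3,3
Fz,3,5
F4,3,7
F8,3,9
FC5,4,2
FC1,4,4
FC2,4,6
FC6,4,8
T7,5,1
C3,5,3
Cz,5,5
C4,5,7
T8,5,9
CP5,6,2
CP1,6,4
CP2,6,6
CP6,6,8
P7,7,1
P3,7,3
Pz,7,5
P4,7,7
P8,7,9
PO3,8,4
PO4,8,6
O1,9,4
Oz,9,5
O2,9,6
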