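name,row,col
AF3,2,4
AF4,2,6
F7,3,1
F3,3,3
F4,3,7
F8,3,9
FC5,4,2
FC6,4,8
T7,5,1
T8,5,9
P7,7,1
P8,7,9
O1,9,4
O2,9,6
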