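reference,N,S,V
N,41931,2146,181
S,98,1673,66
V,52,144,3025
F,333,1,54
Q,4,0,3
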