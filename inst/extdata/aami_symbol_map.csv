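symbol,aami_class,description
N,N,normal beat
L,N,left bundle branch block beat
R,N,right bundle branch block beat
e,N,atrial escape beat
j,N,nodal (junctional) escape beat
A,S,atrial premature beat
a,S,aberrated atrial premature beat
J,S,nodal (junctional) premature beat
S,S,supraventricular premature beat
V,V,premature ventricular contraction
E,V,ventricular escape beat
F,F,fusion of ventricular and normal beat
/,Q,paced beat
f,Q,fusion of paced and normal beat
Q,Q,unclassifiable beat
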