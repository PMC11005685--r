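code,charge,lj_epsilon,lj_sigma,radius,mass
CHOL,0,1.5,6,3,40
A,0,0.2,4.5,2.25,10
C,0,0.2,4.5,2.25,10
D,-1,0.2,4.5,2.25,10
E,-1,0.2,4.5,2.25,10
F,0,0.2,4.5,2.25,10
G,0,0.2,4.5,2.25,10
H,0,0.2,4.5,2.25,10
I,0,0.2,4.5,2.25,10
K,1,0.2,4.5,2.25,10
L,0,0.2,4.5,2.25,10
M,0,0.2,4.5,2.25,10
N,0,0.2,4.5,2.25,10
P,0,0.2,4.5,2.25,10
Q,0,0.2,4.5,2.25,10
R,1,0.2,4.5,2.25,10
S,0,0.2,4.5,2.25,10
T,0,0.2,4.5,2.25,10
V,0,0.2,4.5,2.25,10
W,0,0.2,4.5,2.25,10
Y,0,0.2,4.5,2.25,10
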