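# Synthetic per-amino-acid-type chemical-shift and temperature-coefficient
# statistics. Approximates random-coil behaviour for simulation and testing;
# NOT literature reference values. Shifts in ppm, TCs in ppb/K.
# Glycine has no CB entries; proline has no HN entries.
type,feature,mean,sd
A,HN,8.25,0.12
A,TC1_HN,-5.15,1.2
A,TC2_HN,-4.85,1.2
A,N,123.8,1.6
A,TC1_N,-1.4,1.5
A,TC2_N,-1.1,1.5
A,C,177.8,0.55
A,TC1_C,-2.7,1
A,TC2_C,-2.4,1
A,CA,52.5,0.45
A,TC1_CA,-0.23,1
A,TC2_CA,0.07,1
A,CB,19.1,0.6
A,TC1_CB,-1.06,1
A,TC2_CB,-0.76,1
C,HN,8.32,0.12
C,TC1_HN,-5.49,1.2
C,TC2_HN,-5.19,1.2
C,N,118.8,1.6
C,TC1_N,0.39,1.5
C,TC2_N,0.69,1.5
C,C,174.6,0.55
C,TC1_C,-0.21,1
C,TC2_C,0.09,1
C,CA,58.2,0.45
C,TC1_CA,-0.82,1
C,TC2_CA,-0.52,1
C,CB,28,0.6
C,TC1_CB,-1.86,1
C,TC2_CB,-1.56,1
D,HN,8.34,0.12
D,TC1_HN,-4.49,1.2
D,TC2_HN,-4.19,1.2
D,N,120.4,1.6
D,TC1_N,-1.35,1.5
D,TC2_N,-1.05,1.5
D,C,176.3,0.55
D,TC1_C,-1.82,1
D,TC2_C,-1.52,1
D,CA,54.2,0.45
D,TC1_CA,-1.86,1
D,TC2_CA,-1.56,1
D,CB,41.1,0.6
D,TC1_CB,0.4,1
D,TC2_CB,0.7,1
E,HN,8.42,0.12
E,TC1_HN,-4.16,1.2
E,TC2_HN,-3.86,1.2
E,N,120.2,1.6
E,TC1_N,0.48,1.5
E,TC2_N,0.78,1.5
E,C,176.6,0.55
E,TC1_C,-3.58,1
E,TC2_C,-3.28,1
E,CA,56.6,0.45
E,TC1_CA,-0.55,1
E,TC2_CA,-0.25,1
E,CB,30,0.6
E,TC1_CB,1.04,1
E,TC2_CB,1.34,1
F,HN,8.3,0.12
F,TC1_HN,-7.38,1.2
F,TC2_HN,-7.08,1.2
F,N,120.3,1.6
F,TC1_N,-0.97,1.5
F,TC2_N,-0.67,1.5
F,C,175.8,0.55
F,TC1_C,-3.05,1
F,TC2_C,-2.75,1
F,CA,57.7,0.45
F,TC1_CA,1.44,1
F,TC2_CA,1.74,1
F,CB,39.6,0.6
F,TC1_CB,-1.2,1
F,TC2_CB,-0.9,1
G,HN,8.35,0.12
G,TC1_HN,-5.04,1.2
G,TC2_HN,-4.74,1.2
G,N,108.8,1.6
G,TC1_N,2.58,1.5
G,TC2_N,2.88,1.5
G,C,174.9,0.55
G,TC1_C,-3.56,1
G,TC2_C,-3.26,1
G,CA,45.3,0.45
G,TC1_CA,1.74,1
G,TC2_CA,2.04,1
H,HN,8.42,0.12
H,TC1_HN,-5.61,1.2
H,TC2_HN,-5.31,1.2
H,N,118.2,1.6
H,TC1_N,1.71,1.5
H,TC2_N,2.01,1.5
H,C,174.8,0.55
H,TC1_C,-1.15,1
H,TC2_C,-0.85,1
H,CA,55,0.45
H,TC1_CA,0.67,1
H,TC2_CA,0.97,1
H,CB,29,0.6
H,TC1_CB,-1.87,1
H,TC2_CB,-1.57,1
I,HN,8,0.12
I,TC1_HN,-6.55,1.2
I,TC2_HN,-6.25,1.2
I,N,120.5,1.6
I,TC1_N,0.61,1.5
I,TC2_N,0.91,1.5
I,C,176.4,0.55
I,TC1_C,-0.71,1
I,TC2_C,-0.41,1
I,CA,61.1,0.45
I,TC1_CA,-0.8,1
I,TC2_CA,-0.5,1
I,CB,38.8,0.6
I,TC1_CB,1.39,1
I,TC2_CB,1.69,1
K,HN,8.29,0.12
K,TC1_HN,-4.95,1.2
K,TC2_HN,-4.65,1.2
K,N,120.4,1.6
K,TC1_N,2.98,1.5
K,TC2_N,3.28,1.5
K,C,176.6,0.55
K,TC1_C,-2.68,1
K,TC2_C,-2.38,1
K,CA,56.2,0.45
K,TC1_CA,-0.29,1
K,TC2_CA,0.01,1
K,CB,33.1,0.6
K,TC1_CB,1.21,1
K,TC2_CB,1.51,1
L,HN,8.16,0.12
L,TC1_HN,-4.67,1.2
L,TC2_HN,-4.37,1.2
L,N,121.8,1.6
L,TC1_N,-1.93,1.5
L,TC2_N,-1.63,1.5
L,C,177.6,0.55
L,TC1_C,-1.81,1
L,TC2_C,-1.51,1
L,CA,55.1,0.45
L,TC1_CA,-0.61,1
L,TC2_CA,-0.31,1
L,CB,42.4,0.6
L,TC1_CB,0.26,1
L,TC2_CB,0.56,1
M,HN,8.28,0.12
M,TC1_HN,-5.01,1.2
M,TC2_HN,-4.71,1.2
M,N,119.6,1.6
M,TC1_N,1.52,1.5
M,TC2_N,1.82,1.5
M,C,176.3,0.55
M,TC1_C,-0.13,1
M,TC2_C,0.17,1
M,CA,55.4,0.45
M,TC1_CA,0.06,1
M,TC2_CA,0.36,1
M,CB,32.9,0.6
M,TC1_CB,-1.41,1
M,TC2_CB,-1.11,1
N,HN,8.38,0.12
N,TC1_HN,-5.21,1.2
N,TC2_HN,-4.91,1.2
N,N,118.7,1.6
N,TC1_N,2.25,1.5
N,TC2_N,2.55,1.5
N,C,175.2,0.55
N,TC1_C,-0.6,1
N,TC2_C,-0.3,1
N,CA,53.1,0.45
N,TC1_CA,-1.34,1
N,TC2_CA,-1.04,1
N,CB,38.9,0.6
N,TC1_CB,0.05,1
N,TC2_CB,0.35,1
P,N,137,1.6
P,TC1_N,-0.97,1.5
P,TC2_N,-0.67,1.5
P,C,177.3,0.55
P,TC1_C,-1.97,1
P,TC2_C,-1.67,1
P,CA,63.3,0.45
P,TC1_CA,-1.72,1
P,TC2_CA,-1.42,1
P,CB,32.1,0.6
P,TC1_CB,-0.21,1
P,TC2_CB,0.09,1
Q,HN,8.32,0.12
Q,TC1_HN,-6.02,1.2
Q,TC2_HN,-5.72,1.2
Q,N,119.8,1.6
Q,TC1_N,-1.42,1.5
Q,TC2_N,-1.12,1.5
Q,C,175.9,0.55
Q,TC1_C,-0.47,1
Q,TC2_C,-0.17,1
Q,CA,55.7,0.45
Q,TC1_CA,1.02,1
Q,TC2_CA,1.32,1
Q,CB,29.4,0.6
Q,TC1_CB,-0.95,1
Q,TC2_CB,-0.65,1
R,HN,8.27,0.12
R,TC1_HN,-5.67,1.2
R,TC2_HN,-5.37,1.2
R,N,121.2,1.6
R,TC1_N,2,1.5
R,TC2_N,2.3,1.5
R,C,176.3,0.55
R,TC1_C,-3.95,1
R,TC2_C,-3.65,1
R,CA,56,0.45
R,TC1_CA,1.75,1
R,TC2_CA,2.05,1
R,CB,30.9,0.6
R,TC1_CB,-0.56,1
R,TC2_CB,-0.26,1
S,HN,8.31,0.12
S,TC1_HN,-4.1,1.2
S,TC2_HN,-3.8,1.2
S,N,115.7,1.6
S,TC1_N,1.85,1.5
S,TC2_N,2.15,1.5
S,C,174.6,0.55
S,TC1_C,-1.47,1
S,TC2_C,-1.17,1
S,CA,58.3,0.45
S,TC1_CA,-1.07,1
S,TC2_CA,-0.77,1
S,CB,63.8,0.6
S,TC1_CB,-1.3,1
S,TC2_CB,-1,1
T,HN,8.24,0.12
T,TC1_HN,-6.32,1.2
T,TC2_HN,-6.02,1.2
T,N,113.6,1.6
T,TC1_N,2.15,1.5
T,TC2_N,2.45,1.5
T,C,174.7,0.55
T,TC1_C,-2.06,1
T,TC2_C,-1.76,1
T,CA,61.8,0.45
T,TC1_CA,1.39,1
T,TC2_CA,1.69,1
T,CB,69.8,0.6
T,TC1_CB,-1.01,1
T,TC2_CB,-0.71,1
V,HN,8.03,0.12
V,TC1_HN,-5.01,1.2
V,TC2_HN,-4.71,1.2
V,N,119.2,1.6
V,TC1_N,1.54,1.5
V,TC2_N,1.84,1.5
V,C,176.3,0.55
V,TC1_C,-3.89,1
V,TC2_C,-3.59,1
V,CA,62.2,0.45
V,TC1_CA,-1.68,1
V,TC2_CA,-1.38,1
V,CB,32.9,0.6
V,TC1_CB,-1.45,1
V,TC2_CB,-1.15,1
W,HN,7.97,0.12
W,TC1_HN,-7.2,1.2
W,TC2_HN,-6.9,1.2
W,N,121.3,1.6
W,TC1_N,-0.65,1.5
W,TC2_N,-0.35,1.5
W,C,176.1,0.55
W,TC1_C,-0.64,1
W,TC2_C,-0.34,1
W,CA,57.5,0.45
W,TC1_CA,-0.77,1
W,TC2_CA,-0.47,1
W,CB,29.3,0.6
W,TC1_CB,1.59,1
W,TC2_CB,1.89,1
Y,HN,8.25,0.12
Y,TC1_HN,-7.79,1.2
Y,TC2_HN,-7.49,1.2
Y,N,120.3,1.6
Y,TC1_N,2.6,1.5
Y,TC2_N,2.9,1.5
Y,C,175.9,0.55
Y,TC1_C,-3.77,1
Y,TC2_C,-3.47,1
Y,CA,57.9,0.45
Y,TC1_CA,0.23,1
Y,TC2_CA,0.53,1
Y,CB,38.8,0.6
Y,TC1_CB,-1.97,1
Y,TC2_CB,-1.67,1
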