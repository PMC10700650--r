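aa	rotamer	dx	dy	dz	prior
A	1	0.00	0.00	0.00	1
G	1	0.00	0.00	0.00	1
S	1	0.70	0.00	0.00	1
C	1	0.90	0.00	0.00	1
T	1	0.80	0.00	0.00	1
V	1	0.80	0.00	0.00	1
P	1	0.60	0.00	0.00	1
D	1	1.20	0.00	0.00	0.3334
D	2	1.00	0.70	0.00	0.3333
D	3	1.00	-0.70	0.00	0.3333
N	1	1.20	0.00	0.00	0.3334
N	2	1.00	0.70	0.00	0.3333
N	3	1.00	-0.70	0.00	0.3333
L	1	1.30	0.00	0.00	0.3334
L	2	1.05	0.80	0.00	0.3333
L	3	1.05	-0.80	0.00	0.3333
I	1	1.30	0.00	0.00	0.3334
I	2	1.05	0.80	0.00	0.3333
I	3	1.05	-0.80	0.00	0.3333
M	1	1.80	0.00	0.00	0.3334
M	2	1.40	1.00	0.00	0.3333
M	3	1.40	-1.00	0.00	0.3333
Q	1	1.80	0.00	0.00	0.3334
Q	2	1.40	1.00	0.00	0.3333
Q	3	1.40	-1.00	0.00	0.3333
E	1	1.80	0.00	0.00	0.3334
E	2	1.40	1.00	0.00	0.3333
E	3	1.40	-1.00	0.00	0.3333
K	1	2.20	0.00	0.00	0.3334
K	2	1.70	1.30	0.00	0.3333
K	3	1.70	-1.30	0.00	0.3333
R	1	2.50	0.00	0.00	0.3334
R	2	1.90	1.50	0.00	0.3333
R	3	1.90	-1.50	0.00	0.3333
H	1	1.90	0.00	0.00	0.3334
H	2	1.50	1.10	0.00	0.3333
H	3	1.50	-1.10	0.00	0.3333
F	1	2.00	0.00	0.00	0.3334
F	2	1.60	1.20	0.00	0.3333
F	3	1.60	-1.20	0.00	0.3333
Y	1	2.40	0.00	0.00	0.3334
Y	2	1.90	1.40	0.00	0.3333
Y	3	1.90	-1.40	0.00	0.3333
W	1	2.30	0.00	0.00	0.3334
W	2	1.80	1.40	0.00	0.3333
W	3	1.80	-1.40	0.00	0.3333
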