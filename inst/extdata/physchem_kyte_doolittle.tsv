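residue	hydrophobicity	charge
A	1.8	0
R	-4.5	1
N	-3.5	0
D	-3.5	-1
C	2.5	0
Q	-3.5	0
E	-3.5	-1
G	-0.4	0
H	-3.2	0
I	4.5	0
L	3.8	0
K	-3.9	1
M	1.9	0
F	2.8	0
P	-1.6	0
S	-0.8	0
T	-0.7	0
W	-0.9	0
Y	-1.3	0
V	4.2	0
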