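code,name,monoisotopic_mass
G,Glycine,57.021464
A,Alanine,71.037114
S,Serine,87.032028
P,Proline,97.052764
V,Valine,99.068414
T,Threonine,101.047678
C,Cysteine,103.009185
L,Leucine,113.084064
I,Isoleucine,113.084064
N,Asparagine,114.042927
D,Aspartate,115.026943
Q,Glutamine,128.058578
K,Lysine,128.094963
E,Glutamate,129.042593
M,Methionine,131.040485
H,Histidine,137.058912
F,Phenylalanine,147.068414
R,Arginine,156.101111
Y,Tyrosine,163.063329
W,Tryptophan,186.079313
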