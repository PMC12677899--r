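key,value,units,source,version
A,1.8,dimensionless,"Kyte & Doolittle (1982) J Mol Biol 157:105-132",1982
R,-4.5,dimensionless,"Kyte & Doolittle (1982) J Mol Biol 157:105-132",1982
N,-3.5,dimensionless,"Kyte & Doolittle (1982) J Mol Biol 157:105-132",1982
D,-3.5,dimensionless,"Kyte & Doolittle (1982) J Mol Biol 157:105-132",1982
C,2.5,dimensionless,"Kyte & Doolittle (1982) J Mol Biol 157:105-132",1982
Q,-3.5,dimensionless,"Kyte & Doolittle (1982) J Mol Biol 157:105-132",1982
E,-3.5,dimensionless,"Kyte & Doolittle (1982) J Mol Biol 157:105-132",1982
G,-0.4,dimensionless,"Kyte & Doolittle (1982) J Mol Biol 157:105-132",1982
H,-3.2,dimensionless,"Kyte & Doolittle (1982) J Mol Biol 157:105-132",1982
I,4.5,dimensionless,"Kyte & Doolittle (1982) J Mol Biol 157:105-132",1982
L,3.8,dimensionless,"Kyte & Doolittle (1982) J Mol Biol 157:105-132",1982
K,-3.9,dimensionless,"Kyte & Doolittle (1982) J Mol Biol 157:105-132",1982
M,1.9,dimensionless,"Kyte & Doolittle (1982) J Mol Biol 157:105-132",1982
F,2.8,dimensionless,"Kyte & Doolittle (1982) J Mol Biol 157:105-132",1982
P,-1.6,dimensionless,"Kyte & Doolittle (1982) J Mol Biol 157:105-132",1982
S,-0.8,dimensionless,"Kyte & Doolittle (1982) J Mol Biol 157:105-132",1982
T,-0.7,dimensionless,"Kyte & Doolittle (1982) J Mol Biol 157:105-132",1982
W,-0.9,dimensionless,"Kyte & Doolittle (1982) J Mol Biol 157:105-132",1982
Y,-1.3,dimensionless,"Kyte & Doolittle (1982) J Mol Biol 157:105-132",1982
V,4.2,dimensionless,"Kyte & Doolittle (1982) J Mol Biol 157:105-132",1982
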