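# pepscreen residue property table, version 2026.1
# avg_mass: standard average residue (monomer minus water) masses, Da.
# sc_donors: side-chain H-bond donor ATOMS (N/O bearing >=1 H, neutral form).
#   Arg guanidine contributes 3 (NE, NH1, NH2); thiol S-H is not counted.
# sc_acceptors: side-chain N/O atoms excluding amide nitrogens (Asn/Gln side
#   amide N excluded; Trp pyrrole N excluded; His contributes its
#   pyridine-type imidazole N; Arg guanidine nitrogens counted).
# logp_side: Fauchere-Pliska octanol side-chain hydrophobicity increments.
residue	avg_mass	sc_donors	sc_acceptors	logp_side
A	71.0788	0	0	0.31
R	156.1875	3	3	-1.01
N	114.1038	1	1	-0.60
D	115.0886	1	2	-0.77
C	103.1388	0	0	1.54
Q	128.1307	1	1	-0.22
E	129.1155	1	2	-0.64
G	57.0519	0	0	0.00
H	137.1411	1	1	0.13
I	113.1594	0	0	1.80
L	113.1594	0	0	1.70
K	128.1741	1	1	-0.99
M	131.1926	0	0	1.23
F	147.1766	0	0	1.79
P	97.1167	0	0	0.72
S	87.0782	1	1	-0.04
T	101.1051	1	1	0.26
V	99.1326	0	0	1.22
W	186.2132	1	0	2.25
Y	163.1760	1	1	0.96
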