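# Cleavage-specificity table: prolyl endopeptidase (PREP, EC 3.4.21.26).
# Cleaves on the C-terminal side of Pro residues, with two documented
# restrictions: (i) it only acts on substrates of at most 30 residues,
# (ii) Pro-Pro contexts block it -- no cleavage when P1' is Pro, and no
# cleavage after the second Pro of a Pro-Pro pair (P2 = Pro), so peptides
# ending in -Pro-Pro survive.
name: prep
ec: 3.4.21.26
version: 2026.1
substrate_max_len: 30
source: prolyl oligopeptidase specificity; Pro-Pro blocking rule
rule: P1=P ; block: P1'=P ; block: P2=P
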