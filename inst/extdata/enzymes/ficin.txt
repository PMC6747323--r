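# Cleavage-specificity table: ficin (EC 3.4.22.3), cysteine endopeptidase
# from Ficus latex. Papain-family specificity with a stronger preference for
# aromatic residues at P2 and tolerance of Gly/Ser at P1; proline at P1'
# blocks. Edit to match a particular specificity-database snapshot.
name: ficin
ec: 3.4.22.3
version: 2026.1
source: MEROPS C01.006 specificity summary (papain-like, aromatic P2)
rule: P2=FLVWY ; block: P1'=P
rule: P1=GS P2=!P ; block: P1'=P
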