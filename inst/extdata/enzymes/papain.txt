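# Cleavage-specificity table: papain (EC 3.4.22.2), cysteine endopeptidase.
# Encodes the classical Schechter-Berger subsite preference: cleavage is
# driven by a bulky hydrophobic residue in the S2 pocket (P2 of the
# substrate); proline at P1' blocks. Specificity databases differ in the
# exact P2 set they list for papain; edit this file to match a particular
# snapshot (the engine re-reads it at load time).
name: papain
ec: 3.4.22.2
version: 2026.1
source: Schechter-Berger subsite model; MEROPS C01.001 specificity summary
rule: P2=AFILVWY ; block: P1'=P
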