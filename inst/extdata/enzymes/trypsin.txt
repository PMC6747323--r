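# Cleavage-specificity table: trypsin (EC 3.4.21.4). Cleaves C-terminal to
# Lys/Arg, not before Pro, with the documented Keil exception triplets
# (CKD, DKD, CKH, CKY for Lys; CRK, RRH, RRR for Arg) and the two
# pro-tolerant overrides (WKP, MRP cleave despite Pro at P1').
name: trypsin
ec: 3.4.21.4
version: 2026.1
source: Keil (1992) rules as used by web digestion predictors
rule: P1=K P1'=!P ; block: P2=C P1'=D ; block: P2=D P1'=D ; block: P2=C P1'=H ; block: P2=C P1'=Y
rule: P1=R P1'=!P ; block: P2=C P1'=K ; block: P2=R P1'=H ; block: P2=R P1'=R
rule: P2=W P1=K P1'=P
rule: P2=M P1=R P1'=P
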