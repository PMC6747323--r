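# Cleavage-specificity table: chymotrypsin, high-specificity variant
# (EC 3.4.21.1). Cleaves C-terminal to Phe/Tyr (not before Pro) and to Trp
# (not before Pro or Met). The low-specificity variant would add Leu/Met/His
# at P1; the high-specificity set is the one used for conservative
# gastrointestinal-stability prediction.
name: chymotrypsin_high
ec: 3.4.21.1
version: 2026.1
source: Keil (1992) rules as used by web digestion predictors
rule: P1=FY P1'=!P
rule: P1=W P1'=!PM
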