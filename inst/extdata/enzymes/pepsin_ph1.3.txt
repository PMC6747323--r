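# Cleavage-specificity table: pepsin at pH 1.3 (EC 3.4.23.1), the
# high-stringency gastric variant used for gastrointestinal-stability
# prediction. Keil-rule model as documented for the common web digestion
# predictors: cleavage at bonds with Phe/Leu in P1 or P1', suppressed by
# Pro at P2, P1' or P2' and by His/Lys/Arg at P3 (P1-side rule) or at P1
# (P1'-side rule). All "not X" constraints are constrained offsets: a
# position outside the peptide fails the match, so very short peptides
# carrying terminal Phe/Leu are predicted stable.
name: pepsin_ph1.3
ec: 3.4.23.1
version: 2026.1
source: Keil (1992) rules as used by web digestion predictors, pH 1.3 set
rule: P3=!HKR P2=!P P1=FL P1'=!P P2'=!P
rule: P2=!P P1=!HKRP P1'=FL P2'=!P
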