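# pepscreen fixture: allergenicity/toxicity verdicts for the 30 screened
# squid-myosin peptides, in the file-backed predicate format consumed by the
# screening cascade (verdicts as produced by external predictors; all 30
# final peptides are non-allergenic and non-toxic). Version 2026.1.
sequence	allergen	toxin
AF	no	no
AG	no	no
AH	no	no
ASL	no	no
AY	no	no
DY	no	no
IF	no	no
IL	no	no
IR	no	no
PG	no	no
PH	no	no
PPK	no	no
QK	no	no
SF	no	no
SG	no	no
ST	no	no
TF	no	no
TP	no	no
VAF	no	no
VF	no	no
VP	no	no
NAIP	no	no
AK	no	no
IIY	no	no
NH	no	no
NPM	no	no
NPPK	no	no
QM	no	no
QY	no	no
SI	no	no
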