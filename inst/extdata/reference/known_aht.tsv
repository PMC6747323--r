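# pepscreen known-antihypertensive-peptide reference, version 2026.1
# Sequences previously reported as antihypertensive/ACE-inhibitory; used by
# classify_novel() to partition screened candidates into known vs novel.
sequence
AF
AG
AH
ASL
AY
DY
IF
IL
IR
PG
PH
PPK
QK
SF
SG
ST
TF
TP
VAF
VF
VP
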