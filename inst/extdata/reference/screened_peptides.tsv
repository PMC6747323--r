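# pepscreen fixture: the 30 squid-myosin ACE-inhibitory peptides that
# survive the full screening cascade (gastrointestinal stability,
# allergenicity, toxicity, rule-of-5 permeability), with their known/new
# status. Version 2026.1.
sequence	status
AF	known
AG	known
AH	known
ASL	known
AY	known
DY	known
IF	known
IL	known
IR	known
PG	known
PH	known
PPK	known
QK	known
SF	known
SG	known
ST	known
TF	known
TP	known
VAF	known
VF	known
VP	known
NAIP	new
AK	new
IIY	new
NH	new
NPM	new
NPPK	new
QM	new
QY	new
SI	new
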