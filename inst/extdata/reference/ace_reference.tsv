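# pepscreen ACE-inhibitory reference table, version 2026.1
# Di-/tripeptides with literature pIC50 (-log10 molar IC50) used for the
# known-activity lookup stage. Longer entries are permitted in the table but
# are flagged by the loader (the lookup stage matches length 2-3 only).
# Sources are the public bioactive-peptide databases plus measured values for
# the squid-myosin peptides characterised alongside this workflow.
sequence	pIC50	source
MF	6.04	bioactive peptide databases
IY	5.68	bioactive peptide databases
DG	5.67	bioactive peptide databases
EY	5.57	bioactive peptide databases
ST	5.39	bioactive peptide databases
VF	5.04	bioactive peptide databases
AY	4.85	maize hydrolysate, bioactive peptide databases
IIY	4.58	squid myosin heavy chain (measured)
NPPK	4.41	squid myosin heavy chain (measured)
MNPPK	3.02	porcine skeletal muscle hydrolysate
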