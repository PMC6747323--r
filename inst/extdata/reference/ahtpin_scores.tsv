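# pepscreen fixture: SVM regression scores for tetra- to hexapeptides as
# returned by an external activity-prediction web server (file-backed scorer
# input format: sequence <TAB> score). Version 2026.1.
sequence	score
PIYT	1.06
EKSR	1.00
AINPYR	0.99
VIQY	0.91
EPIVK	0.87
QEQDH	0.86
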