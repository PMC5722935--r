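# Calibrated pKa set reproducing the charge columns of the bundled peptide
# reference table at pH 2 and pH 10 (see the package vignette for how each
# value is pinned by the printed charges).
name: table1
nterm: 7.7
cterm: 2.95
D: 3.65
E: 4.25
C: 8.5
"Y": 10.0
H: 6.0
K: 10.0
R: 12.0
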