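# Sillero & Ribeiro (1989) pKa values.
name: sillero
nterm: 8.2
cterm: 3.2
D: 4.0
E: 4.5
C: 9.0
"Y": 10.0
H: 6.4
K: 10.4
R: 12.0
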