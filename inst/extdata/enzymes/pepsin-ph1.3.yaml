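# Pepsin at pH 1.3 (Keil-style specificity): as the pH > 2 variant but the
# hydrophobic set at P1/P1' is restricted to F and L.
enzyme: pepsin
variant: pH1.3
termini: permissive
rules:
  - action: license
    constraints:
      - {position: P1, match: in, residues: FL}
      - {position: P3, match: not_in, residues: HKR}
      - {position: P2, match: not_in, residues: P}
      - {position: P2p, match: not_in, residues: P}
  - action: license
    constraints:
      - {position: P1p, match: in, residues: FL}
      - {position: P1, match: not_in, residues: R}
      - {position: P3, match: not_in, residues: HKR}
      - {position: P2, match: not_in, residues: P}
      - {position: P2p, match: not_in, residues: P}
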