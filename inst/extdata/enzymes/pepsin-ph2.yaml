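# Pepsin at pH > 2 (Keil-style specificity as used by common cleavage-site
# predictors): cleavage when P1 or P1' is F, L, W or Y, except when P3 is
# H/K/R, P2 is P, P2' is P, or (for the P1' branch) P1 is R.
# termini: permissive means a context position falling outside the chain
# satisfies "not_in" exception constraints; "in" constraints always require
# an actual residue.
enzyme: pepsin
variant: pH>2
termini: permissive
rules:
  - action: license
    constraints:
      - {position: P1, match: in, residues: FLWY}
      - {position: P3, match: not_in, residues: HKR}
      - {position: P2, match: not_in, residues: P}
      - {position: P2p, match: not_in, residues: P}
  - action: license
    constraints:
      - {position: P1p, match: in, residues: FLWY}
      - {position: P1, match: not_in, residues: R}
      - {position: P3, match: not_in, residues: HKR}
      - {position: P2, match: not_in, residues: P}
      - {position: P2p, match: not_in, residues: P}
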