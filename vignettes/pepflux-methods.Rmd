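---
title: "pepflux: models, calibrations and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pepflux: models, calibrations and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepflux)
```

# Scope

`pepflux` models the computational chain behind valorising a by-product
protein through enzymatic hydrolysis and membrane fractionation: in silico
protease digestion and the theoretical ceiling on the degree of hydrolysis
(DH), pH-stat DH curves, mass-based peptide identification from
chromatographic peak lists, physicochemical profiling with pI-based
grouping, and ultrafiltration transmission/selectivity analysis. The
worked substrate is mature bovine serum albumin (BSA, UniProt P02769
residues 25–607; 583 residues, 582 peptide bonds), bundled as a FASTA
fixture. A seeded synthetic-data generator emulates the chromatograms the
laboratory stages would produce, so the whole chain is testable without
instrument data.

# In silico digestion

Cleavage specificity is declarative: a rule set is a list of constraints
over the P4–P4′ window of each peptide bond, each rule either licensing
or vetoing cleavage, with veto precedence. The packaged pepsin tables
follow the Keil-style rules used by common cleavage-site predictors:
cleavage when P1 or P1′ is F/L (pH 1.3 variant) or F/L/W/Y (pH > 2
variant), except when P3 is H/K/R, P2 is P, P2′ is P, or — for the P1′
branch — P1 is R.

Two policies govern context positions that fall outside the chain. Under
`termini: blocking` a missing position fails every constraint; under
`permissive` a missing position satisfies the *exception* ("not_in")
constraints — an absent residue cannot be a forbidden one — while
license ("in") constraints always require an actual residue. The package
default is the pH > 2 variant with permissive termini. That pairing is a
calibration result: on the bundled mature BSA it yields exactly 147
cleavable bonds out of 582 and hence

$$\mathrm{DH_{max}} = 100 \times \frac{147}{582} = 25.26\%,$$

the published calibration point for this substrate–enzyme pair, whereas
the pH 1.3 variant gives 123–124 sites and blocking termini give 146.
The single bond affected by the terminus policy is the penultimate one
(…QTAL‑A). Both variants and both policies remain selectable.

```{r digest}
protein <- bsaMature()
map <- findCleavageSites(protein, pepsinRules("pH>2"))
map
```

Peptide enumeration offers specific (cleavage-bounded fragments with a
missed-cleavage budget), semi-specific and non-specific (every substring)
modes; the quadratic modes refuse parents above a configurable length cap
(default 1000 residues). Coordinates are 1-based inclusive; bond *i*
joins residues *i* and *i*+1, which is what makes the 583-residue chain
have 582 bonds.

# Masses and identification

Peptide masses are residue sums plus water, with one proton added for
the singly protonated form. All identification arithmetic uses
monoisotopic [M+H]⁺ masses because identification tables for ESI peak
lists print that form (the bundled reference table's MW column is
reproduced to ≤ 0.007 Da across all 43 entries). Matching is
FindPept-style: every pool peptide within an absolute tolerance (default
±0.3 Da, the usual setting for this instrument class; ppm matching is a
trivial user-side variation) and above a minimum length (default 3) is a
candidate. A peak is *unique* when its candidates reduce to one distinct
sequence — repeat occurrences of the same sequence at different
coordinates do not create ambiguity — *ambiguous* at two or more, else
*unmatched*. Peak lists are pre-processed by merging peaks within
0.005 Da (areas summed, area-weighted mean mass) and by the
relative-intensity rule that discards peaks at or below 10% of the base
peak.

Stream reconciliation applies the campaign-level exclusion rules:
accepted identifications are the unique hydrolysate matches; ambiguous
hydrolysate masses and masses seen only in permeates are excluded with
reason codes, so every excluded mass lands in exactly one category of
the log.

# Physicochemical profile

GRAVY is the arithmetic mean of Kyte–Doolittle hydropathies. Net charge
at pH follows the Henderson–Hasselbalch summation with free termini and
the D/E/C/Y/H/K/R side chains ionisable; the charge is strictly
decreasing in pH, so the isoelectric point is the unique zero crossing,
located by bisection on [0, 14] to 10⁻³ pH units. Groups follow the
fractionation convention acid (pI < 5), basic (pI > 8), neutral
otherwise; boundary values classify neutral because the strict
inequalities leave them to the enclosing interval.

No published pKa set is canonical for reproducing a given server's
output, so the package ships EMBOSS-, Sillero- and Lehninger-style
tables plus a calibrated default (`"table1"`) fitted against the bundled
reference table's charge columns. The calibration is tightly pinned by
the printed values themselves: termini-only peptides print +0.90 at
pH 2, forcing the C-terminal pKa to 2 + log₁₀(9) ≈ 2.95; lysine-bearing
peptides printing integer charges at pH 10 force Lys ≈ 10.0; the
recurring −0.50 tyrosine contribution at pH 10 forces Tyr ≈ 10.0; and
−1.00 for termini-only peptides at pH 10 caps the N-terminal pKa below
about 7.9 (7.7 shipped, the midpoint of the admissible plateau). Under
this table all 86 printed charges are matched within ±0.036 and 41 of
43 group labels are reproduced. The two exceptions, HTLF and HVKLVNE,
are printed as basic but have pI ≈ 6.7–6.8 under *every* standard pKa
set (their only basic groups are one His plus the N-terminus); no
physically sensible table moves them above 8, so the package reports
the computed classification. Similarly, two GRAVY entries of the
reference table (ACFAVE, VAF) are inconsistent with the Kyte–Doolittle
scale itself (1.60 and 2.93 by direct computation against 0.87 and 2.90
as printed); the package always reports computed hydropathies.

# pH-stat degree of hydrolysis

The titration form is

$$\mathrm{DH}(\%) = \frac{100 \, A \, N_A}{(1-\alpha)\, h_{TOT}\, M_p},$$

with every factor in the denominator — the printed one-line form of this
equation is ambiguous about grouping, and this is the standard pH-stat
reading consistent with the DH literature. Defaults are the study
conditions: α = 0.325, h_TOT = 8.8 meq/g, M_p = 3 g, N_A = 0.1 meq/mL
(the titrant normality is not stated by the source protocol; 0.1 N is
the field-typical choice and is freely overridable). α is consumed as a
constant; estimating it from temperature and amino-group pK is out of
scope. Relative DH rescales by DH_max. Non-monotone titrant series are
clamped to their running maximum with a warning. The plateau onset is
the first time after which every subsequent relative-DH gain per
15-minute interval (both configurable) stays below 1 percentage point.

# Membrane transmission and selectivity

Observed transmission is the permeate-to-feed peak-area ratio,
Tr(%) = 100·A_P/A_H; values above 100% are retained and flagged as
quantitation anomalies rather than truncated, since area-based
chromatographic quantitation can legitimately produce them. The
theoretical (purely steric) transmission uses the sieving form

$$\lambda = \left(\frac{MW}{MWCO}\right)^{0.4},\qquad
\mathrm{Tr}(\%) = 100\,[1-(\lambda(\lambda-2))^2]\,e^{-0.7146\lambda^2},$$

clamped to 0 for λ ≥ 1: the raw polynomial rebounds to positive values
on 1 < λ < 2, which is unphysical for a sieving coefficient. Separation
factors are ratios of group-mean transmissions; by default peptides
undetected in the permeate contribute Tr = 0 to their group mean
(averaging over *all* group members, which is what makes near-total
rejection produce very large but finite factors), with a detected-only
mode available because the convention is not uniquely determined. A zero
denominator returns a flagged infinity rather than an error.

# The synthetic-data generator

`simulationConfig()` encodes the study design as defaults: the BSA
substrate under the calibrated pepsin rules, two polyethersulfone
membranes (PES1 = 1 kDa, PES5 = 5 kDa) at pH 2 and pH 10, and a 0–180
min pH-stat grid sampled every 15 min. Hydrolysate peaks get lognormal
ground-truth abundances (meanlog log 10⁵, sdlog 1 — a typical dynamic
range for UPLC peak areas), multiplicative lognormal area noise
(σ = 0.2) and optional Gaussian mass jitter (0.01 Da). The pH-stat curve
is first-order, A(t) = A_inf(1 − e^{−kt}) with additive noise; A_inf =
29.5 mL is chosen so that the asymptotic *relative* DH under the Eq-1
defaults is ≈ 65.5% of DH_max — the headline extent of hydrolysis for
this substrate — and k = 0.03 min⁻¹ reproduces the qualitative curve
shape (steep first 15 min, plateau from ~120 min).

The filtration ground truth multiplies the sieving coefficient by a
logistic attenuation in |net charge at operating pH|,
2/(1 + e^{β|z|}), and a hydrophobic-retention penalty
e^{−γ·max(0, GRAVY − g₀)}. This is a *synthetic construction* for
testing: it encodes, qualitatively, the finding that charge state
dominates the sieve effect and that hydrophobic peptides interact with
polyethersulfone, but it is not a literature transmission model and is
never used by the analysis stages themselves. With β = γ = 0 and zero
noise the generator reduces exactly to the sieving model, which is the
lever the recovery tests use. All draws flow from one seed; filtration
conditions and pH-stat replicates advance documented sub-seed offsets,
so ground-truth structure is shared across seeds and only noise
realisations change.

What the generator does not emulate — chromatographic retention times,
co-elution, isotope envelopes, fouling and concentration polarisation,
enzyme kinetics beyond the first-order titrant curve — bounds what
passing tests show about real data: they validate the arithmetic and the
statistical contracts of the pipeline, not instrument physics.

# Numerical choices and test scale

Internal arithmetic is unrounded; report tables round half away from
zero at 2 decimals. Bisection tolerance for pI is 10⁻³ pH units.
Mass-window lookups widen the tolerance by 10⁻⁹ Da so boundary
candidates are kept. The test suite runs the digestion oracle on random
chains of 6–40 residues, brute-force enumeration equivalence up to 30
residues, all-pairs matching on 50 × 200 problems, distributional checks
on 1000-peptide simulations and kinetic recovery over 50 pH-stat
replicates; the full simulated pipeline runs with 30–40 peptides per
report. These sizes keep the suite in the seconds range while leaving
every statistical assertion comfortably powered.

# Known limitations

Bioactivity scores are consumed as data (the upstream neural scorer is
out of scope), disulfide-linked species and modified residues are not
modelled, and the identification layer starts from peak lists — spectral
processing upstream of them is explicitly not reimplemented. The
reference-table discordances discussed above (two GRAVY entries, two
group labels) are reported as computed; the package does not arbitrate
between a printed table and its own arithmetic.
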