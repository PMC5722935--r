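Package: pepflux
Title: In Silico Proteolysis and Membrane Fractionation of Protein Hydrolysates
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for valorising protein by-products through enzymatic
    hydrolysis and ultrafiltration. Implements rule-based in silico
    proteolysis with declarative cleavage grammars (pepsin rule sets
    included), theoretical maximum degree of hydrolysis, peptide pool
    enumeration, monoisotopic and average peptide masses, FindPept-style
    mass matching of chromatographic peak lists with tolerance and
    exclusion rules, physicochemical annotation (Kyte-Doolittle GRAVY,
    Henderson-Hasselbalch net charge, isoelectric point by bisection,
    pI-based acid/basic/neutral grouping), pH-stat degree-of-hydrolysis
    curves, ultrafiltration sieving-model transmissions, separation
    factors, and a seeded synthetic-data generator that emulates
    hydrolysate and permeate chromatograms with recoverable ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    minpack.lm
Config/testthat/edition: 3
biocViews: Proteomics, MassSpectrometry, Software
RoxygenNote: 7.3.3
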