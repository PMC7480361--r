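Package: lactopep
Title: Intracellular Peptidomics of Lactococcus lactis Peptidase Mutants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-processing toolkit for intracellular peptidomics of
    Lactococcus lactis peptidase deletion strains degrading bovine
    beta-casein. Computes monoisotopic peptide masses with modifications and
    ppm mass errors, applies replicate-consensus filtering to
    peptide-identification tables, localizes peptides on substrate proteins
    and builds per-residue coverage profiles with gap detection, summarizes
    peptide physicochemical properties, curates and matches multi-source
    bioactive-peptide databases with UpSet-style activity intersection
    counts, and generates synthetic identification tables by stochastic
    in-silico proteolysis shaped by peptidase-class cleavage rules and
    knockout genotypes.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, tools, Biostrings, BiocGenerics
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
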