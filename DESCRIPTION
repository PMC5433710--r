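Package: mitocons
Title: Conservation and Disease-Variant Analysis of Primate Mitochondrial Protein Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative analysis of mitochondrial protein-coding genes across a
    primate phylogeny. Computes per-aligned-codon conservation indices (distinct
    amino-acid counts, parsimony-counted non-synonymous substitutions, and
    empirical-Bayes standardized site rates), SLAC-style dN/dS counting with an
    extended-binomial test for negative selection, radical physicochemical
    amino-acid change detection over 31 property scales, and maps human mtDNA
    disease-associated variants (MITOMAP-style m.-notation, rCRS coordinates,
    overlapping reading frames, light-strand genes) onto aligned codon columns to
    count clade presence, independent evolutionary origins and reversions. A
    seeded codon-model simulator with full event-log ground truth supports
    end-to-end validation without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    phangorn,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
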