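Package: meganumt
Title: Discriminating Multi-Copy Nuclear Mitochondrial Insertions from
    Heteroplasmy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Inference chain for deciding whether a mixed mitochondrial
    DNA signature reflects true heteroplasmy (or biparental inheritance)
    or a multi-copy nuclear insertion of the mitogenome (Mega-NUMT).
    Parses rCRS-relative mitotypes with IUPAC mixed-base codes, performs
    phylogenetically guided two-source deconvolution, scores haplogroup
    plausibility against motif tables, integrates tissue-contrast
    evidence from nucleated, anucleate and mtDNA-depleted cells, checks
    Mendelian pedigree segregation of the insertion allele, and
    estimates the tandem copy number and insert size from droplet
    digital and real-time PCR quantification. Includes a seeded
    generative model of family datasets for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
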