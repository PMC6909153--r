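Package: cnidopep
Title: Annotation of Multi-Copy Neuropeptide Preprohormones in Cnidarian
    Sequence Data
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Discovers neuropeptide preprohormones in translated cnidarian
    genomes and transcriptomes by detecting tandem arrays of similar peptide
    cassettes flanked by classical prohormone-convertase processing sites,
    predicts mature peptides from explicit processing chemistry (basic-site
    cleavage, glycine-donated C-terminal amidation, N-terminal aminopeptidase
    trimming with pyroglutamate and proline stops), groups peptides into
    cross-class families with C-terminally anchored consensus motifs, and
    reconstructs preprohormone phylogenies (Fitch parsimony and
    neighbor-joining on p-distance). A synthetic-data generator with ground
    truth makes the whole pipeline testable without any sequence downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    phangorn,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    yaml
Config/testthat/edition: 3
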