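Package: lavauth
Title: Combined DNA-Barcoding and Chemical-Fingerprint Authentication of
    Lavandula Species
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for authenticating lavender (Lavandula)
    raw material by combining two independent lines of evidence: DNA barcoding
    with three markers (rbcL, trnH-psbA and a Lavandula-specific ITS marker)
    and a rule-based chemotaxonomic key evaluated on UHPLC peak tables. The
    genetic half performs degenerate-primer in-silico PCR, paired-read
    consensus, p-distance computation, UPGMA tree building with nonparametric
    bootstrap support, marker concatenation and identical-sequence
    (haplotype-group) discrimination analysis. The chemical half matches
    chromatographic peaks to a reference compound library by retention time
    and evaluates a seven-criterion presence/absence key that assigns each
    sample to one of six chemotypic clusters. A synthetic-data module
    generates an eleven-taxon reference panel (ten Lavandula accessions plus
    the outgroup Perovskia atriplicifolia) so the whole pipeline can be run
    and tested without physical samples.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
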