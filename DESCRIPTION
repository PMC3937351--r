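Package: reticulITS
Title: Hybridization Signatures from Cloned Nuclear Ribosomal ITS Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects the molecular signatures of hybridization in rapidly
    radiating plant groups from cloned nuclear ribosomal internal transcribed
    spacer (ITS) sequences. Provides clone-error filtering (removal of
    singleton polymorphisms attributable to PCR polymerase error),
    identification of divergent intra-individual ITS versions, a pseudogene
    screen based on three conserved 5.8S motifs and GC content relative to a
    functional reference, hybrid-ancestry classification by a
    minimum-difference distance criterion, tandem-repeat detection by
    wraparound alignment, simple indel coding of alignment gaps, and
    detection of clade-membership incongruence between nuclear and
    chloroplast phylogenies. A radiation simulator with hybridization
    events, chloroplast capture, concerted-evolution homogenization and
    per-clone PCR error makes every stage of the pipeline verifiable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    Biostrings,
    phangorn,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
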