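Package: neoscan
Title: Tumour-Specific Neoantigen Prediction from Paired Somatic Variant Calls
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts candidate tumour-specific neoantigens from paired
    tumour-normal somatic variant calls. Applies a depth/VAF somatic filter,
    derives protein-level consequences (missense and frameshift) on transcript
    models, enumerates 8-11-mer MHC class I candidate peptides from 21-residue
    mutation contexts, classifies wild-type versus mutant HLA binding by IC50,
    maps missense mutations to extracellular regions of membrane proteins with
    polarity-change annotation, and aggregates cohort-level recurrence and
    neoantigen-load statistics. Includes a deterministic toy affinity backend,
    a NetMHCpan output parser, and a synthetic fixture cohort generator so the
    whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    vcfR,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
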