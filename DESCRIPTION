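Package: hla2present
Title: HLA Class II Peptide Presentation by Cross-Attention
    Multiple-Instance Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Trains and applies a transformer-based multiple-instance model
    of peptide presentation by HLA class II molecules.  Every 9-residue
    window of a peptide is scored against every allele of a sample through
    a cross-attention interaction encoder, and the sample-level
    presentation score is the maximum over all window-allele pairs.
    Includes the full training protocol (per-epoch proteome decoys,
    cluster-size loss weighting, allele dropout, two-scenario ensembling),
    a planted-motif synthetic data generator with ground-truth binding
    cores, antibody immunogenicity screening with germline filtering and
    hotspot heatmaps, neoantigen tiering, binding-core entropy profiles,
    and attention-versus-contact-map analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    Biostrings,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    pROC
Config/testthat/edition: 3
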