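Package: methsig
Title: Cell-Type and Disease DNA Methylation Signatures from Two-Colour CpG Panel Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Discovery of cell-type-specific and disease-associated DNA
    methylation signatures from two-colour CpG bead-array panels of the
    GoldenGate type.  Implements the full analysis chain: probe filtering
    (X chromosome, SNP-containing probes, detection failures), K-nearest-
    neighbour imputation of detection-failed measurements, background and
    colour-bias correction, distance-weighted-discrimination (DWD) batch
    adjustment, M-value computation and per-sample z-score standardisation,
    per-CpG two-group testing with Storey q-value FDR estimation and a dual
    q-value / z-difference calling rule, signature set algebra with Venn
    decomposition, and hypergeometric functional enrichment against a
    user-supplied annotation.  A synthetic-data generator emulating a
    matched airway-epithelium / blood paediatric study design provides a
    ground-truth test bed for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
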