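Package: resibind
Title: Per-Residue Protein-DNA Binding Site Prediction from Language-Model Embeddings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Predicts DNA-binding residues of a protein from per-residue
    embeddings using a four-layer one-dimensional convolutional network
    trained with a joint objective: a class-balanced focal loss (effective
    number reweighting) for the heavily imbalanced binary labels, plus a
    triplet center loss with learnable class centers that shapes a
    discriminative per-residue feature space. Includes FASTA and label-track
    I/O, a pluggable embedder contract with a deterministic windowed one-hot
    fallback, structure-based binding-site labeling via a van der Waals
    distance rule, imbalance-aware evaluation metrics (MCC, ROC/PR curves,
    AUC, AUPR, amino-acid composition and KL divergence), and a seeded
    synthetic-data generator so the full pipeline is testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    bio3d,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
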