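Package: lysotype
Title: Phage Lifestyle Classification from Protein-Cluster Token Sentences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies bacteriophage contigs as virulent or temperate by
    reading each contig as a sentence of protein-cluster tokens. A token
    vocabulary is built by Markov clustering of an all-against-all protein
    similarity graph; contigs are tokenized gene-by-gene via best alignment to
    cluster representatives; a bidirectional transformer encoder is pretrained
    with a masked-token objective over unlabeled genomes and fine-tuned on
    lifestyle-labeled, length-augmented fragments. Includes evaluation metrics
    (sensitivity, specificity, accuracy, ROC/AUC with temperate as the positive
    class) and a seeded synthetic-universe generator so the full pipeline runs
    without downloads or external aligners.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
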