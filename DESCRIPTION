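Package: adjuvantnet
Title: Neural-Network Analysis of Vaccine Adjuvant Transcriptomic Signatures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for classifying vaccine-adjuvant groups from blood
    transcriptomic fold-change profiles and for predicting post-vaccination
    antibody titers from early (day-1) gene expression. Implements the full
    analysis path: FPKM log-transformation with pseudo-count, low-intensity
    gene filtering, ortholog mapping, immune-panel selection and per-animal
    baseline fold changes; a fully connected single-hidden-layer neural
    network (ReLU, softmax or linear head) trained by mini-batch gradient
    descent; balanced k-fold cross-validation with majority-class
    undersampling and confusion-matrix metrics; a random-forest comparison
    arm; weight-product saliency analysis of the trained network with gene
    ranking and inter-group correlation reports; and principal component and
    heatmap summaries. A synthetic-cohort generator with planted group
    signatures and expression-driven antibody titers makes every stage
    testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, jsonlite, randomForest
Suggests: testthat (>= 3.0.0), pheatmap, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
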