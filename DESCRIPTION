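Package: lnccnn
Title: Interpretable 1D Convolutional Classification of Long Non-Coding RNA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Distinguishes long non-coding RNA (lncRNA) transcripts from
    protein-coding transcripts (mRNA) directly from nucleotide sequence using a
    one-dimensional convolutional neural network trained on one-hot encoded
    transcripts, and explains each call with additive per-nucleotide
    attributions computed against a background set of reference sequences.
    Attributions are aggregated to codons in all three reading frames and to
    k-mer impact summaries, and rendered as colour tracks along the transcript.
    Includes FASTA preprocessing with length filtering and stratified
    splitting, a synthetic transcript simulator with planted open reading
    frames and motifs for ground-truth benchmarking, a full evaluation suite
    (confusion metrics, ROC/AUC, accuracy by length bin), and a command-line
    workflow.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    pROC,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    broom,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
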