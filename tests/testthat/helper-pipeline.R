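# Shared end-to-end fixture: one synthetic dataset with a planted motif,
# one scaled-profile model trained on it, and attributions for the held-out
# test set. Built lazily on first use and cached for the whole test run
# (training is the expensive step); every consumer sees identical objects
# because all seeds are fixed.

.pipeline_cache <- new.env(parent = emptyenv())

pipeline_fixture <- function() {
  if (!is.null(.pipeline_cache$pipe)) {
    return(.pipeline_cache$pipe)
  }
  spec <- synthetic_spec(n_per_class = 200L, length_range = c(200L, 600L),
                         motif = default_motif(), motif_rate = 1,
                         seed = 11L)
  sim <- generate_transcripts(spec)
  split <- stratified_split(sim$records, test_fraction = 0.2, seed = 12L)
  config <- scaled_model_config(seed = 13L)
  enc_train <- encode_dataset(split$train, config$input_length)
  enc_test <- encode_dataset(split$test, config$input_length)
  model <- train_model(build_model(config), enc_train)
  preds <- predict(model, enc_test)
  background <- select_background(enc_train, n_per_class = 20L, seed = 14L)
  expl <- compute_shap(model, background, enc_test)
  tracks <- lapply(expl$explanations, collapse_to_nucleotide)
  names(tracks) <- vapply(expl$explanations, `[[`, "", "seq_id")
  .pipeline_cache$pipe <- list(
    spec = spec, sim = sim, split = split, config = config,
    enc_train = enc_train, enc_test = enc_test, model = model,
    preds = preds, background = background, expl = expl, tracks = tracks)
  .pipeline_cache$pipe
}

# mean |codon attribution| inside vs outside the annotated motif, in the
# motif's own reading frame, for one explained mRNA-like sequence
motif_contrast <- function(explanation, motif_row) {
  track <- collapse_to_nucleotide(explanation)[seq_len(explanation$length)]
  ct <- codon_aggregate(track)
  v <- abs(ct$frames[[as.character(motif_row$frame)]])
  starts <- motif_row$frame + 3L * (seq_along(v) - 1L)
  inside <- starts >= motif_row$start & (starts + 3L) <= motif_row$end
  c(inside = mean(v[inside]), outside = mean(v[!inside]))
}

extdata <- function(file) {
  system.file("extdata", file, package = "lnccnn", mustWork = TRUE)
}

# records tibble shorthand for small hand-built cases
recs <- function(ids, seqs, labels = NULL) {
  out <- tibble::tibble(id = ids, seq = seqs)
  if (!is.null(labels)) out$label <- labels
  out
}
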