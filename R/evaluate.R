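#' Confusion counts with lncRNA as the positive class
#'
#' TP: lncRNA predicted lncRNA; TN: mRNA predicted mRNA; FP: mRNA predicted
#' lncRNA; FN: lncRNA predicted mRNA.
#'
#' @param truth A tibble with columns `id` and `label`.
#' @param predictions A predictions tibble with columns `id` and
#'   `predicted_label` (as returned by [predict.lnc_cnn()]).
#' @return A one-row tibble of class `confusion_counts` with columns `TP`,
#'   `FP`, `TN`, `FN`.
#' @export
confusion <- function(truth, predictions) {
  truth <- tibble::as_tibble(truth)
  predictions <- tibble::as_tibble(predictions)
  if (anyDuplicated(truth$id) || anyDuplicated(predictions$id)) {
    stop("duplicate ids in truth or predictions", call. = FALSE)
  }
  if (!setequal(truth$id, predictions$id)) {
    off <- c(setdiff(truth$id, predictions$id),
             setdiff(predictions$id, truth$id))
    stop("ids do not match one-to-one; e.g. ",
         paste(utils::head(off, 5L), collapse = ", "), call. = FALSE)
  }
  check_labels(truth$label)
  check_labels(predictions$predicted_label)
  pred <- predictions$predicted_label[match(truth$id, predictions$id)]
  out <- tibble::tibble(
    TP = sum(truth$label == "lncRNA" & pred == "lncRNA"),
    FP = sum(truth$label == "mRNA" & pred == "lncRNA"),
    TN = sum(truth$label == "mRNA" & pred == "mRNA"),
    FN = sum(truth$label == "lncRNA" & pred == "mRNA"))
  class(out) <- c("confusion_counts", class(out))
  out
}

#' Build confusion counts directly from the four tallies
#'
#' @param TP,FP,TN,FN Non-negative counts.
#' @return A `confusion_counts` tibble.
#' @export
confusion_counts <- function(TP, FP, TN, FN) {
  stopifnot(TP >= 0, FP >= 0, TN >= 0, FN >= 0)
  out <- tibble::tibble(TP = TP, FP = FP, TN = TN, FN = FN)
  class(out) <- c("confusion_counts", class(out))
  out
}

#' Round half away from zero
#'
#' Decimal rounding with the "round half up" convention used for printed
#' percentage tables (in contrast to [round()]'s round-half-even).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Classification metrics from confusion counts
#'
#' Accuracy, sensitivity (recall of lncRNA), specificity, precision and
#' F1 (harmonic mean of precision and sensitivity), all on the 0-100
#' percentage scale at full precision; use [round_half_up()] (or the print
#' method) for the conventional 2-decimal display. Metrics with a zero
#' denominator are `NA`, never silently 0.
#'
#' @param counts A `confusion_counts` row (or any data frame with columns
#'   `TP`, `FP`, `TN`, `FN`).
#' @param auc Optional AUC (proportion in `[0, 1]`) carried alongside.
#' @return A one-row tibble of class `metrics_report`.
#' @export
metrics <- function(counts, auc = NA_real_) {
  counts <- tibble::as_tibble(counts)
  stopifnot(all(c("TP", "FP", "TN", "FN") %in% names(counts)))
  with(counts, {
    total <- TP + FP + TN + FN
    if (any(total == 0)) stop("all four counts are zero", call. = FALSE)
    frac <- function(num, den) ifelse(den > 0, 100 * num / den, NA_real_)
    sens <- frac(TP, TP + FN)
    prec <- frac(TP, TP + FP)
    out <- tibble::tibble(
      accuracy = frac(TP + TN, total),
      sensitivity = sens,
      specificity = frac(TN, TN + FP),
      precision = prec,
      f1 = ifelse(!is.na(prec) & !is.na(sens) & (prec + sens) > 0,
                  2 * prec * sens / (prec + sens), NA_real_),
      auc = auc)
    class(out) <- c("metrics_report", class(out))
    out
  })
}

#' @export
print.metrics_report <- function(x, ...) {
  shown <- x
  for (col in c("accuracy", "sensitivity", "specificity", "precision",
                "f1")) {
    shown[[col]] <- round_half_up(x[[col]], 2L)
  }
  print(as.data.frame(shown), row.names = FALSE)
  invisible(x)
}

#' ROC curve and AUC for the lncRNA score
#'
#' The score is `p_lncRNA`, positives are lncRNA. The AUC equals the
#' Mann-Whitney probability that a random positive outscores a random
#' negative, ties counted half (trapezoidal curve).
#'
#' @param scores Numeric vector of lncRNA probabilities (or any monotone
#'   score).
#' @param labels Character vector of true labels (`lncRNA`/`mRNA`).
#' @return A list with `curve` (tibble: `threshold`, `fpr`, `tpr`, monotone
#'   in both coordinates) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  check_labels(labels)
  if (length(unique(labels)) < 2L) {
    stop("ROC needs both classes present", call. = FALSE)
  }
  roc <- pROC::roc(response = labels, predictor = scores,
                   levels = c("mRNA", "lncRNA"), direction = "<",
                   quiet = TRUE)
  ord <- order(1 - roc$specificities, roc$sensitivities)
  curve <- tibble::tibble(threshold = roc$thresholds[ord],
                          fpr = (1 - roc$specificities)[ord],
                          tpr = roc$sensitivities[ord])
  list(curve = curve, auc = as.numeric(pROC::auc(roc)))
}

#' Accuracy stratified by sequence length
#'
#' @param predictions A predictions tibble (`id`, `predicted_label`).
#' @param truth A tibble with `id` and `label`.
#' @param lengths Named (by id) or aligned-with-`truth` vector of sequence
#'   lengths.
#' @param bin_edges Increasing edges; bin i is `[e_i, e_{i+1})`, the last
#'   bin closed. Defaults to width-280 bins over `[200, 3000]`.
#' @return A `LengthBinTable` tibble: `bin`, `lo`, `hi`, `n`, `accuracy`
#'   (`NA` with `empty = TRUE` for empty bins).
#' @export
accuracy_by_length <- function(predictions, truth, lengths,
                               bin_edges = seq(200L, 3000L, by = 280L)) {
  stopifnot(length(bin_edges) >= 2L, !is.unsorted(bin_edges, strictly = TRUE))
  truth <- tibble::as_tibble(truth)
  if (!is.null(names(lengths))) lengths <- lengths[truth$id]
  stopifnot(length(lengths) == nrow(truth))
  if (any(lengths < bin_edges[1L] | lengths > bin_edges[length(bin_edges)])) {
    stop("sequence length outside the binned range [", bin_edges[1L], ", ",
         bin_edges[length(bin_edges)], "]", call. = FALSE)
  }
  pred <- predictions$predicted_label[match(truth$id, predictions$id)]
  correct <- pred == truth$label
  bin <- findInterval(lengths, bin_edges, rightmost.closed = TRUE)
  nb <- length(bin_edges) - 1L
  purrr::map_dfr(seq_len(nb), function(i) {
    in_bin <- bin == i
    n <- sum(in_bin)
    tibble::tibble(bin = i, lo = bin_edges[i], hi = bin_edges[i + 1L],
                   n = n,
                   accuracy = if (n > 0L) 100 * mean(correct[in_bin])
                              else NA_real_,
                   empty = n == 0L)
  })
}

#' Annotation-summary percentage
#'
#' `100 * numerator / denominator`, rounded half-up to two decimals — the
#' arithmetic behind summary tables such as "fraction of true positives
#' carrying a protein-domain annotation".
#'
#' @param numerator,denominator Counts with
#'   `0 <= numerator <= denominator`, `denominator > 0`.
#' @return The percentage, two decimals.
#' @export
annotation_summary_pct <- function(numerator, denominator) {
  stopifnot(all(denominator > 0), all(numerator >= 0),
            all(numerator <= denominator))
  round_half_up(100 * numerator / denominator, 2L)
}

#' Read / write prediction TSV files
#'
#' @param path TSV path with columns `id`, `p_lncRNA`, `p_mRNA`,
#'   `predicted_label`.
#' @return A predictions tibble.
#' @export
read_predictions <- function(path) {
  if (!file.exists(path)) stop("predictions file not found: ", path,
                               call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("id", "p_lncRNA", "p_mRNA", "predicted_label")
  if (!all(need %in% names(df))) {
    stop("predictions file must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(df[, need])
}

#' @rdname read_predictions
#' @param predictions A predictions tibble.
#' @export
write_predictions <- function(predictions, path) {
  utils::write.table(predictions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
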