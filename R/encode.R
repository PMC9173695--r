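#' Filter transcripts by length
#'
#' Transcripts shorter than `min_len` or longer than `max_len` are discarded;
#' the closed interval `[min_len, max_len]` is kept. The defaults keep
#' sequences between 200 and 3000 nt, the usual working range for
#' lncRNA/mRNA classification.
#'
#' @param records A records tibble with columns `id` and `seq`.
#' @param min_len,max_len Inclusive length bounds.
#' @return A list with elements `records` (the kept tibble) and `report`
#'   (a one-row tibble: `total`, `below_min`, `above_max`, `kept`,
#'   `min_len`, `max_len`).
#' @seealso [length_filter_report()] for the report alone from a length
#'   vector.
#' @export
filter_by_length <- function(records, min_len = 200L, max_len = 3000L) {
  records <- as_records(records, need_label = FALSE)
  lens <- nchar(records$seq)
  report <- length_filter_report(lens, min_len, max_len)
  keep <- lens >= min_len & lens <= max_len
  list(records = records[keep, , drop = FALSE], report = report)
}

#' Length-filter bookkeeping from a vector of lengths
#'
#' @param lengths Integer vector of sequence lengths.
#' @param min_len,max_len Inclusive bounds.
#' @return A one-row tibble with columns `total`, `below_min`, `above_max`,
#'   `kept`, `min_len`, `max_len`; `kept = total - below_min - above_max`
#'   always holds.
#' @export
length_filter_report <- function(lengths, min_len = 200L, max_len = 3000L) {
  stopifnot(min_len >= 1L, max_len >= min_len)
  below <- sum(lengths < min_len)
  above <- sum(lengths > max_len)
  tibble::tibble(total = length(lengths), below_min = below,
                 above_max = above, kept = length(lengths) - below - above,
                 min_len = as.integer(min_len), max_len = as.integer(max_len))
}

#' One-hot encode a nucleotide sequence
#'
#' Each position becomes a row over the fixed channel order (A, C, G, T).
#' Unambiguous bases set exactly one channel to 1; ambiguity codes (N, R, Y,
#' ...) give an all-zero row, as do padding rows beyond the sequence end.
#'
#' @param seq A single nucleotide string (already normalised; see
#'   [read_fasta()]).
#' @param max_len Pad (with all-zero rows) to this many rows. Sequences longer
#'   than `max_len` are an error: filter or truncate first.
#' @return A `max_len` x 4 numeric matrix with colnames `A,C,G,T`.
#' @export
one_hot_encode <- function(seq, max_len = 3000L) {
  stopifnot(is.character(seq), length(seq) == 1L)
  L <- nchar(seq)
  if (L > max_len) {
    stop("sequence length ", L, " exceeds max_len ", max_len,
         "; filter or truncate first", call. = FALSE)
  }
  m <- matrix(0, nrow = max_len, ncol = 4L,
              dimnames = list(NULL, c("A", "C", "G", "T")))
  if (L == 0L) return(m)
  bases <- strsplit(seq, "", fixed = TRUE)[[1L]]
  ch <- match(bases, c("A", "C", "G", "T"))
  ok <- !is.na(ch)
  m[cbind(which(ok), ch[ok])] <- 1
  m
}

#' Decode a one-hot matrix back to a sequence
#'
#' Inverse of [one_hot_encode()] on unambiguous bases: rows with a single 1
#' decode to that base, all-zero rows within `length` decode to `N`.
#'
#' @param mat A one-hot matrix.
#' @param length Number of leading rows that are real sequence (the rest is
#'   padding). Defaults to all rows.
#' @return A nucleotide string.
#' @export
decode_one_hot <- function(mat, length = nrow(mat)) {
  if (length == 0L) return("")
  rows <- mat[seq_len(length), , drop = FALSE]
  idx <- max.col(rows, ties.method = "first")
  idx[rowSums(rows) == 0] <- NA
  paste(ifelse(is.na(idx), "N", c("A", "C", "G", "T")[idx]), collapse = "")
}

#' Encode a labelled record set into a training tensor
#'
#' Builds the N x Lmax x 4 array the network consumes, right-padded with
#' all-zero rows. lncRNA is the positive class (index 1), mRNA the negative
#' class (index 0).
#'
#' @param records A records tibble with `id`, `seq` and (unless
#'   `require_labels = FALSE`) `label`.
#' @param max_len Model input length; sequences longer than this are an error.
#' @param require_labels Set `FALSE` for prediction-time encoding without
#'   labels.
#' @return An object of class `encoded_dataset`: a list with `tensor`
#'   (N x max_len x 4), `labels` (factor, levels `mRNA`, `lncRNA`; `NULL` if
#'   unlabelled), `lengths`, `ids` and `max_len`.
#' @export
encode_dataset <- function(records, max_len = 3000L, require_labels = TRUE) {
  records <- as_records(records, need_label = require_labels)
  n <- nrow(records)
  lens <- nchar(records$seq)
  too_long <- which(lens > max_len)
  if (length(too_long) > 0L) {
    stop("sequence(s) longer than max_len ", max_len, ": ",
         paste(utils::head(records$id[too_long], 5L), collapse = ", "),
         call. = FALSE)
  }
  tensor <- array(0, dim = c(n, max_len, 4L))
  for (i in seq_len(n)) {
    tensor[i, , ] <- one_hot_encode(records$seq[[i]], max_len)
  }
  labels <- NULL
  if ("label" %in% names(records) && !anyNA(records$label)) {
    labels <- factor(records$label, levels = lnc_classes())
  }
  structure(list(tensor = tensor, labels = labels, lengths = lens,
                 ids = records$id, max_len = as.integer(max_len)),
            class = "encoded_dataset")
}

#' @export
print.encoded_dataset <- function(x, ...) {
  cat("<encoded_dataset> ", length(x$ids), " sequences x ", x$max_len,
      " nt x 4 channels\n", sep = "")
  if (!is.null(x$labels)) print(table(x$labels))
  invisible(x)
}

# subset an encoded dataset by row index
subset_encoded <- function(x, i) {
  structure(list(tensor = x$tensor[i, , , drop = FALSE],
                 labels = if (is.null(x$labels)) NULL else x$labels[i],
                 lengths = x$lengths[i], ids = x$ids[i],
                 max_len = x$max_len),
            class = "encoded_dataset")
}

#' Stratified train/test split
#'
#' Splits labelled records into train and test sets, drawing the test set
#' per class so that class proportions are preserved to within one record.
#' Deterministic for a given seed.
#'
#' @param records A labelled records tibble; every record must have a label
#'   and each class at least two records.
#' @param test_fraction Proportion held out (default 0.20).
#' @param seed Integer seed.
#' @return A list with tibbles `train` and `test` (disjoint, jointly
#'   exhaustive).
#' @export
stratified_split <- function(records, test_fraction = 0.2, seed = 1L) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  records <- as_records(records, need_label = TRUE)
  cls <- split(seq_len(nrow(records)), records$label)
  small <- names(cls)[vapply(cls, length, 1L) < 2L]
  if (length(small) > 0L) {
    stop("each class needs >= 2 records; too few: ",
         paste(small, collapse = ", "), call. = FALSE)
  }
  test_idx <- integer(0)
  withr::with_seed(seed, {
    for (nm in sort(names(cls))) {
      idx <- cls[[nm]]
      n_test <- round(length(idx) * test_fraction)
      n_test <- max(1L, min(length(idx) - 1L, n_test))
      test_idx <- c(test_idx, sample(idx, n_test))
    }
  })
  test_idx <- sort(test_idx)
  list(train = records[-test_idx, , drop = FALSE],
       test = records[test_idx, , drop = FALSE])
}
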