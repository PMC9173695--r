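#' Read transcript sequences from a FASTA file
#'
#' Reads a (possibly multi-line) FASTA file into a tibble of transcript
#' records. Residues are normalised on the way in: lowercase is uppercased and
#' RNA `U` is mapped to DNA `T`, so downstream code works on a single DNA
#' alphabet. IUPAC ambiguity codes (`N`, `R`, `Y`, ...) are preserved.
#' The record id is the header token before the first whitespace.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id`, `seq` and `length`.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">tx1 some description", "ACGUacgu", ">tx2", "NNTT"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    return(tibble::tibble(id = character(), seq = character(),
                          length = integer()))
  }
  ids <- sub("\\s.*$", "", names(set))
  seqs <- unname(normalize_residues(as.character(set)))
  bad <- which(!nzchar(seqs))
  if (length(bad) > 0L) {
    stop("FASTA entry with empty sequence: ",
         paste(ids[bad], collapse = ", "), call. = FALSE)
  }
  nohdr <- which(!nzchar(ids))
  if (length(nohdr) > 0L) {
    stop("FASTA entry #", nohdr[1L], " has an empty header", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate sequence ids in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  tibble::tibble(id = ids, seq = seqs, length = nchar(seqs))
}

# uppercase and U -> T; whitespace inside bodies is already handled by the
# FASTA parser
normalize_residues <- function(x) {
  chartr("U", "T", toupper(x))
}

#' Write transcript records to a FASTA file
#'
#' @param records A data frame with columns `id` and `seq`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  records <- as_records(records, need_label = FALSE)
  set <- Biostrings::BStringSet(stats::setNames(records$seq, records$id))
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Read a two-column label table
#'
#' Labels accompany a FASTA file as a headerless or headered TSV with columns
#' `id` and `label`, where label is `lncRNA` or `mRNA`.
#'
#' @param path Path to a TSV file.
#' @return A tibble with columns `id` and `label`.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("label file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  header <- grepl("^id\\t", first)
  df <- utils::read.delim(path, header = header, sep = "\t",
                          col.names = c("id", "label"),
                          colClasses = "character")
  check_labels(df$label)
  tibble::tibble(id = df$id, label = df$label)
}

#' Write a label table
#'
#' @param records A data frame with columns `id` and `label`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(records, path) {
  utils::write.table(records[, c("id", "label")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Attach labels to sequence records
#'
#' @param records A records tibble (from [read_fasta()]).
#' @param labels A label tibble (from [read_labels()]) or a character vector
#'   aligned with `records`.
#' @return `records` with a `label` column.
#' @export
attach_labels <- function(records, labels) {
  records <- as_records(records, need_label = FALSE)
  if (is.character(labels) && is.null(dim(labels))) {
    stopifnot(length(labels) == nrow(records))
    check_labels(labels)
    records$label <- labels
    return(records)
  }
  labels <- tibble::as_tibble(labels)
  missing <- setdiff(records$id, labels$id)
  if (length(missing) > 0L) {
    stop("no label for record(s): ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  }
  records$label <- labels$label[match(records$id, labels$id)]
  records
}

#' Drop exact duplicate sequences
#'
#' A lightweight stand-in for similarity-based deduplication: only
#' byte-identical sequences (after residue normalisation) are collapsed,
#' keeping the first occurrence.
#'
#' @param records A records tibble.
#' @return The deduplicated tibble.
#' @export
dedup_exact <- function(records) {
  records <- as_records(records, need_label = FALSE)
  records[!duplicated(records$seq), , drop = FALSE]
}

lnc_classes <- function() c("mRNA", "lncRNA")

check_labels <- function(labels) {
  bad <- setdiff(unique(labels), lnc_classes())
  if (length(bad) > 0L) {
    stop("labels must be 'lncRNA' or 'mRNA'; found: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(labels)
}

# coerce and validate the records contract shared by all modules
as_records <- function(records, need_label = TRUE) {
  records <- tibble::as_tibble(records)
  if (!all(c("id", "seq") %in% names(records))) {
    stop("records must have columns 'id' and 'seq'", call. = FALSE)
  }
  if (nrow(records) > 0L && anyDuplicated(records$id)) {
    stop("record ids must be unique; duplicated: ",
         paste(unique(records$id[duplicated(records$id)]), collapse = ", "),
         call. = FALSE)
  }
  if (need_label) {
    if (!"label" %in% names(records)) {
      stop("records must carry a 'label' column", call. = FALSE)
    }
    unl <- records$id[is.na(records$label)]
    if (length(unl) > 0L) {
      stop("unlabeled record(s): ", paste(utils::head(unl, 10L),
                                          collapse = ", "), call. = FALSE)
    }
    check_labels(records$label[!is.na(records$label)])
  }
  records
}
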