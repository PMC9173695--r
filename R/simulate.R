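#' Specification for a synthetic transcript dataset
#'
#' Describes a two-class synthetic dataset that reproduces the statistical
#' contrast a coding-potential classifier exploits: mRNA-like sequences carry
#' a long open reading frame (5' UTR, ATG, stop-free codon body, one terminal
#' stop codon, 3' UTR, optionally a planted in-frame "domain" motif at known
#' coordinates), while lncRNA-like sequences are i.i.d. nucleotides at the
#' stated GC content and therefore hit an in-frame stop roughly every 3/64
#' codons.
#'
#' @param n_per_class Sequences per class.
#' @param length_range Inclusive range of total transcript lengths in
#'   nucleotides (default `c(200, 3000)`, the classifier's working range).
#' @param utr5_range Inclusive range of 5' UTR lengths (default `c(10, 50)`).
#' @param motif Optional nucleotide string planted in-frame inside mRNA ORFs.
#'   Must have length divisible by 3 and contain no in-frame stop codon.
#'   `default_motif()` gives a 57-nt motif spanning one convolution kernel.
#' @param motif_rate Fraction of mRNA-like sequences carrying the motif.
#' @param gc_content GC proportion for random nucleotides (default 0.5).
#' @param seed Integer seed; generation is fully reproducible.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_per_class, length_range = c(200L, 3000L),
                           utr5_range = c(10L, 50L), motif = NULL,
                           motif_rate = 0, gc_content = 0.5, seed = 1L) {
  stopifnot(n_per_class >= 1L,
            length_range[1] >= 200L, length_range[2] <= 3000L,
            length_range[1] <= length_range[2],
            utr5_range[1] >= 0L, utr5_range[1] <= utr5_range[2],
            motif_rate >= 0, motif_rate <= 1,
            gc_content > 0, gc_content < 1)
  if (!is.null(motif)) {
    motif <- normalize_residues(motif)
    if (nchar(motif) %% 3L != 0L) {
      stop("motif length must be divisible by 3 (planted in-frame)",
           call. = FALSE)
    }
    if (any(codon_split(motif) %in% stop_codons())) {
      stop("motif must not contain an in-frame stop codon", call. = FALSE)
    }
  }
  structure(list(n_per_class = as.integer(n_per_class),
                 length_range = as.integer(length_range),
                 utr5_range = as.integer(utr5_range),
                 motif = motif, motif_rate = motif_rate,
                 gc_content = gc_content, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' @rdname synthetic_spec
#' @export
default_motif <- function() {
  substr(strrep("GATTACA", 9L), 1L, 57L)
}

stop_codons <- function() c("TAA", "TAG", "TGA")

sense_codons <- function() {
  all_codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                  c("A", "C", "G", "T")), 1L, paste0,
                      collapse = "")
  setdiff(all_codons, stop_codons())
}

codon_split <- function(seq) {
  n <- nchar(seq) %/% 3L
  substring(seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

random_nt <- function(n, gc) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Generate a labelled synthetic transcript dataset
#'
#' Draws `n_per_class` mRNA-like and lncRNA-like sequences according to a
#' [synthetic_spec()]. mRNA-like sequences have, by construction, no in-frame
#' stop codon between the ATG and the single terminal stop; lncRNA-like
#' sequences are i.i.d. nucleotides. Planted motifs are reported with 0-based
#' half-open coordinates and the reading frame relative to the sequence
#' start.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `records` (tibble: `id`, `seq`, `label`, `length`,
#'   `orf_start`, `orf_end` — ORF coordinates 0-based half-open, `NA` for
#'   lncRNA-like records) and `motifs` (tibble: `seq_id`, `start`, `end`,
#'   `frame`).
#' @export
generate_transcripts <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  sense <- sense_codons()
  min_body <- if (is.null(spec$motif)) 1L else nchar(spec$motif) %/% 3L
  # smallest admissible transcript: utr5_min + ATG + body + stop
  if (spec$length_range[1] < spec$utr5_range[1] + 6L + 3L * min_body) {
    stop("motif longer than the minimum ORF body for this length range",
         call. = FALSE)
  }
  recs <- vector("list", 2L * spec$n_per_class)
  motifs <- list()
  withr::with_seed(spec$seed, {
    for (i in seq_len(spec$n_per_class)) {
      # --- mRNA-like: 5'UTR + ATG + stop-free body + stop + 3'UTR ---
      L <- sample(spec$length_range[1]:spec$length_range[2], 1L)
      utr5 <- sample(spec$utr5_range[1]:spec$utr5_range[2], 1L)
      utr5 <- min(utr5, L - 6L - 3L * min_body)
      utr3_want <- sample(spec$utr5_range[1]:spec$utr5_range[2], 1L)
      utr3_want <- max(0L, min(utr3_want, L - utr5 - 6L - 3L * min_body))
      n_body <- (L - utr5 - utr3_want - 6L) %/% 3L
      utr3 <- L - utr5 - 6L - 3L * n_body
      body <- sample(sense, n_body, replace = TRUE)
      id <- sprintf("mrna_%04d", i)
      if (!is.null(spec$motif) && stats::runif(1) < spec$motif_rate) {
        k <- nchar(spec$motif) %/% 3L
        at <- sample.int(n_body - k + 1L, 1L)   # codon index within body
        body[at:(at + k - 1L)] <- codon_split(spec$motif)
        start0 <- utr5 + 3L + 3L * (at - 1L)    # 0-based
        motifs[[length(motifs) + 1L]] <- tibble::tibble(
          seq_id = id, start = start0, end = start0 + nchar(spec$motif),
          frame = start0 %% 3L)
      }
      seq <- paste0(random_nt(utr5, spec$gc_content), "ATG",
                    paste(body, collapse = ""),
                    sample(stop_codons(), 1L),
                    random_nt(utr3, spec$gc_content))
      recs[[i]] <- tibble::tibble(id = id, seq = seq, label = "mRNA",
                                  orf_start = utr5,
                                  orf_end = utr5 + 6L + 3L * n_body)
      # --- lncRNA-like: i.i.d. nucleotides ---
      L2 <- sample(spec$length_range[1]:spec$length_range[2], 1L)
      recs[[spec$n_per_class + i]] <- tibble::tibble(
        id = sprintf("lnc_%04d", i),
        seq = random_nt(L2, spec$gc_content), label = "lncRNA",
        orf_start = NA_integer_, orf_end = NA_integer_)
    }
  })
  records <- dplyr::bind_rows(recs)
  records$length <- nchar(records$seq)
  records <- records[, c("id", "seq", "label", "length",
                         "orf_start", "orf_end")]
  motifs <- if (length(motifs) == 0L) {
    tibble::tibble(seq_id = character(), start = integer(),
                   end = integer(), frame = integer())
  } else {
    dplyr::bind_rows(motifs)
  }
  list(records = records, motifs = motifs)
}

#' Mononucleotide shuffle of a sequence
#'
#' Returns a random permutation of the residues, preserving length and
#' composition exactly. Shuffling an mRNA-like sequence destroys its ORF
#' structure (in-frame stops reappear at the background rate), which makes
#' this a useful negative control for the classifier.
#'
#' @param seq A nucleotide string.
#' @param seed Integer seed.
#' @return The shuffled string.
#' @export
shuffle_control <- function(seq, seed = 1L) {
  bases <- strsplit(seq, "", fixed = TRUE)[[1L]]
  withr::with_seed(seed, paste(sample(bases), collapse = ""))
}
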