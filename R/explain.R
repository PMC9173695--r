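#' Select a background reference set for attribution
#'
#' Additive attributions are computed relative to the expected model output
#' over a background distribution; following common practice the background
#' is a class-balanced random subset of the (training) data, 175 sequences
#' per class by default.
#'
#' @param dataset A labelled [encode_dataset()] result.
#' @param n_per_class Sequences drawn per class, without replacement.
#' @param seed Integer seed; selection is deterministic.
#' @return A `background_set` (also an `encoded_dataset`).
#' @export
select_background <- function(dataset, n_per_class = 175L, seed = 1L) {
  stopifnot(inherits(dataset, "encoded_dataset"))
  if (is.null(dataset$labels)) {
    stop("background selection needs a labelled dataset", call. = FALSE)
  }
  idx <- withr::with_seed(seed, {
    picked <- integer(0)
    for (cls in lnc_classes()) {
      avail <- which(dataset$labels == cls)
      if (length(avail) < n_per_class) {
        stop("class ", cls, " has only ", length(avail),
             " sequences; need ", n_per_class, call. = FALSE)
      }
      picked <- c(picked, sample(avail, n_per_class))
    }
    sort(picked)
  })
  bg <- subset_encoded(dataset, idx)
  bg$n_per_class <- as.integer(n_per_class)
  bg$seed <- as.integer(seed)
  class(bg) <- c("background_set", "encoded_dataset")
  bg
}

# replicate the single-sequence (1 x ...) activations across R reference rows
rep_rows <- function(a, R) {
  if (is.matrix(a)) a[rep(1L, R), , drop = FALSE]
  else a[rep(1L, R), , , drop = FALSE]
}

# rescale rule for ReLU: slope of the activation between reference and input
rescale_mult <- function(zx, zr, eps = 1e-7) {
  d <- zx - zr
  m <- (relu(zx) - relu(zr)) / d
  small <- abs(d) < eps
  m[small] <- (zx > 0)[small]
  m
}

# multiplier propagation through a width-2 max-pool: the output delta is
# distributed over the two window inputs proportionally to their own deltas
# (least-norm split), which conserves the delta exactly; degenerate windows
# fall back to routing along the input's argmax.
pool_mult <- function(m_out, ax, ar, Ls) {
  d <- dim(m_out); R <- d[1]; J <- d[2]; C <- d[3]
  odd <- seq(1L, 2L * J, by = 2L); even <- odd + 1L
  dA <- ax[, odd, , drop = FALSE] - ar[, odd, , drop = FALSE]
  dB <- ax[, even, , drop = FALSE] - ar[, even, , drop = FALSE]
  dout <- pmax(ax[, odd, , drop = FALSE], ax[, even, , drop = FALSE]) -
    pmax(ar[, odd, , drop = FALSE], ar[, even, , drop = FALSE])
  den <- dA^2 + dB^2
  wA <- dout * dA / den
  wB <- dout * dB / den
  small <- den < 1e-12
  firstx <- ax[, odd, , drop = FALSE] >= ax[, even, , drop = FALSE]
  wA[small] <- firstx[small]
  wB[small] <- !firstx[small]
  m_in <- array(0, c(R, Ls, C))
  m_in[, odd, ] <- m_out * wA
  m_in[, even, ] <- m_out * wB
  m_in
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Additive attributions for the lncRNA output
#'
#' Computes, for each input sequence, an attribution matrix assigning every
#' (position, channel) entry its contribution to the model's lncRNA
#' probability relative to the background expectation. Contributions are
#' obtained by propagating difference-from-reference multipliers backwards
#' through the network (the rescale rule on ReLU and on the two-class
#' softmax — which reduces to a logistic function of the logit difference —
#' exact linear propagation through convolutions and dense layers, and a
#' delta-conserving split across max-pool windows), then averaging over all
#' background references. The additive ("local accuracy") contract
#' `sum(values) + base_value = p_lncRNA(x)` is checked for every sequence.
#'
#' @param model A trained `lnc_cnn`.
#' @param background A [select_background()] result (or any
#'   `encoded_dataset` to use wholesale).
#' @param sequences An [encode_dataset()] result or records tibble to
#'   explain.
#' @param tol Warn if the additivity residual of any sequence exceeds this
#'   (default 0.05 on the probability scale).
#' @return A `shap_explanations` object: a list of per-sequence attributions,
#'   each with `seq_id`, `values` (input_length x 4 matrix, channels
#'   A,C,G,T), `base_value` (mean background lncRNA probability), `fx`
#'   (the model's lncRNA probability for the sequence), `length` (true
#'   sequence length) and `additivity_error`.
#' @export
compute_shap <- function(model, background, sequences, tol = 0.05) {
  stopifnot(inherits(model, "lnc_cnn"))
  if (!inherits(sequences, "encoded_dataset")) {
    sequences <- encode_dataset(sequences,
                                max_len = model$config$input_length,
                                require_labels = FALSE)
  }
  if (!inherits(background, "encoded_dataset")) {
    stop("background must be a background_set / encoded_dataset",
         call. = FALSE)
  }
  R <- length(background$ids)
  if (R == 0L) stop("background set is empty", call. = FALSE)
  check_input_length(background, model$config)
  check_input_length(sequences, model$config)
  config <- model$config
  params <- model$params
  fwr <- nn_forward(params, config, background$tensor, keep = TRUE)
  p_ref <- fwr$probs[, 2L]
  base_value <- mean(p_ref)
  s_ref <- fwr$logits[, 2L] - fwr$logits[, 1L]
  out <- vector("list", length(sequences$ids))
  for (i in seq_along(sequences$ids)) {
    X <- sequences$tensor[i, , , drop = FALSE]
    fwx <- nn_forward(params, config, X, keep = TRUE)
    m_x <- deeplift_multipliers(params, config, fwx, fwr, s_ref, R)
    diff <- rep_rows(X, R) - background$tensor
    contrib <- m_x * diff                       # R x L x 4
    values <- matrix(colMeans(matrix(contrib, nrow = R)),
                     config$input_length, 4L)
    colnames(values) <- c("A", "C", "G", "T")
    fx <- unname(fwx$probs[1L, 2L])
    err <- sum(values) + base_value - fx
    out[[i]] <- list(seq_id = sequences$ids[i], values = values,
                     base_value = base_value, fx = fx,
                     length = sequences$lengths[i],
                     additivity_error = err)
  }
  worst <- max(abs(vapply(out, `[[`, 1, "additivity_error")))
  if (worst > tol) {
    warning(sprintf(paste0("additivity residual %.4f exceeds tolerance ",
                           "%.4f for at least one sequence"), worst, tol),
            call. = FALSE)
  }
  structure(list(explanations = out, n_background = R,
                 base_value = base_value, input_length = config$input_length),
            class = "shap_explanations")
}

# backward multiplier pass for one explained sequence against R references;
# returns the R x L x 4 input multipliers
deeplift_multipliers <- function(params, config, fwx, fwr, s_ref, R) {
  cx <- fwx$cache; cr <- fwr$cache
  s_x <- fwx$logits[1L, 2L] - fwx$logits[1L, 1L]
  ds <- s_x - s_ref
  m_s <- (sigmoid(s_x) - sigmoid(s_ref)) / ds
  m_s[abs(ds) < 1e-7] <- sigmoid(s_x) * (1 - sigmoid(s_x))
  w_diff <- params$out$W[, 2L] - params$out$W[, 1L]
  m <- m_s %o% w_diff                               # R x H
  nd <- length(config$dense_units)
  for (j in rev(seq_len(nd))) {
    zx <- rep_rows(cx[[paste0("zd", j)]], R)
    m <- m * rescale_mult(zx, cr[[paste0("zd", j)]])
    m <- tcrossprod(m, params$dense[[j]]$W)
  }
  lens <- layer_lengths(config)
  nb <- config$n_conv_blocks
  m <- unflatten3(m, lens[nb], config$filters_per_block)
  for (i in rev(seq_len(nb))) {
    ax <- rep_rows(relu(cx[[paste0("z", i)]]), R)
    ar <- relu(cr[[paste0("z", i)]])
    Ls <- dim(ar)[2]
    m <- pool_mult(m, ax, ar, Ls)
    m <- m * rescale_mult(rep_rows(cx[[paste0("z", i)]], R),
                          cr[[paste0("z", i)]])
    m <- conv1d_backward_input(m, params$conv[[i]]$W,
                               cx[[paste0("conv", i)]]$L,
                               stride = config$stride)
  }
  m
}

#' @export
print.shap_explanations <- function(x, ...) {
  cat("<shap_explanations> ", length(x$explanations), " sequences, ",
      x$n_background, " background references, base value ",
      sprintf("%.4f", x$base_value), "\n", sep = "")
  invisible(x)
}

#' Tidy attributions into a long tibble
#'
#' @param x A `shap_explanations` object.
#' @param ... Unused.
#' @return A tibble with columns `seq_id`, `position` (1-based), `channel`
#'   and `shap_value`, restricted to each sequence's true length.
#' @export
tidy.shap_explanations <- function(x, ...) {
  purrr::map_dfr(x$explanations, function(e) {
    v <- e$values[seq_len(e$length), , drop = FALSE]
    tibble::tibble(seq_id = e$seq_id,
                   position = rep(seq_len(e$length), 4L),
                   channel = rep(c("A", "C", "G", "T"),
                                 each = e$length),
                   shap_value = as.vector(v))
  })
}

#' Collapse channel attributions to one value per nucleotide
#'
#' Sums the four channel values at every position; the total attribution is
#' conserved exactly.
#'
#' @param attr An attribution matrix (L x 4), or one element of a
#'   `shap_explanations` object.
#' @return A numeric vector of per-nucleotide attributions.
#' @export
collapse_to_nucleotide <- function(attr) {
  if (is.list(attr) && !is.null(attr$values)) attr <- attr$values
  stopifnot(is.matrix(attr), ncol(attr) == 4L)
  rowSums(attr)
}

#' Aggregate a nucleotide track into codons in three reading frames
#'
#' Frame `f` (0, 1, 2) sums attributions over consecutive non-overlapping
#' nucleotide triplets starting at offset `f`; incomplete trailing codons
#' are dropped, so frame `f` has `floor((L - f) / 3)` values.
#'
#' @param track A numeric per-nucleotide attribution vector.
#' @return A `codon_tracks` object: list with `frames` (named list of three
#'   numeric vectors) and `length`.
#' @export
codon_aggregate <- function(track) {
  L <- length(track)
  if (L < 3L) stop("need at least 3 nucleotides to form a codon",
                   call. = FALSE)
  frames <- lapply(0:2, function(f) {
    n <- (L - f) %/% 3L
    if (n == 0L) return(numeric(0))
    colSums(matrix(track[(f + 1L):(f + 3L * n)], nrow = 3L))
  })
  names(frames) <- as.character(0:2)
  structure(list(frames = frames, length = L), class = "codon_tracks")
}

#' @export
print.codon_tracks <- function(x, ...) {
  cat("<codon_tracks> sequence of ", x$length, " nt; codons per frame: ",
      paste(lengths(x$frames), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Tidy codon tracks into a tibble
#'
#' @param x A `codon_tracks` object.
#' @param ... Unused.
#' @return A tibble with columns `frame`, `codon` (1-based index within
#'   frame), `start`, `end` (0-based half-open nucleotide coordinates) and
#'   `value`.
#' @export
tidy.codon_tracks <- function(x, ...) {
  purrr::imap_dfr(x$frames, function(v, f) {
    f <- as.integer(f)
    n <- length(v)
    tibble::tibble(frame = f, codon = seq_len(n),
                   start = f + 3L * (seq_len(n) - 1L),
                   end = f + 3L * seq_len(n), value = v)
  })
}

all_kmers <- function(k) {
  base <- c("A", "C", "G", "T")
  out <- base
  if (k > 1L) {
    for (i in seq_len(k - 1L)) {
      out <- as.vector(outer(out, base, paste0))
    }
  }
  sort(out)
}

#' Mean absolute attribution per k-mer
#'
#' Slides a window of width `k` (step 1) along each sequence's true extent,
#' scores each window by the absolute sum of the nucleotide attributions
#' under it, and averages the scores per k-mer identity within each class
#' panel. All `4^k` k-mers appear in the output; k-mers never observed get
#' count 0. Windows containing ambiguity codes are skipped.
#'
#' @param tracks A named list of per-nucleotide attribution vectors, names
#'   matching `records$id`.
#' @param records A labelled records tibble aligned with `tracks`.
#' @param k Window width: 1 (nucleotide), 2 (dinucleotide) or 3 (codon).
#' @param labels Optional grouping labels (e.g. predicted rather than true
#'   class); defaults to `records$label`.
#' @param window_agg `"abs_sum"` (default: absolute value of the window sum)
#'   or `"sum"` (signed window sum).
#' @return A tibble with columns `kmer`, `class`, `mean_abs_shap`, `count`
#'   (`2 * 4^k` rows).
#' @export
kmer_impact <- function(tracks, records, k, labels = NULL,
                        window_agg = c("abs_sum", "sum")) {
  stopifnot(k %in% 1:3)
  window_agg <- match.arg(window_agg)
  records <- as_records(records, need_label = is.null(labels))
  if (is.null(labels)) labels <- records$label
  stopifnot(length(labels) == nrow(records))
  missing <- setdiff(records$id, names(tracks))
  if (length(missing) > 0L) {
    stop("no attribution track for record(s): ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  }
  rows <- purrr::map_dfr(seq_len(nrow(records)), function(i) {
    seq <- records$seq[[i]]
    tr <- tracks[[records$id[[i]]]]
    L <- nchar(seq)
    if (length(tr) < L) {
      stop("track for ", records$id[[i]], " is shorter than its sequence",
           call. = FALSE)
    }
    if (L < k) return(NULL)
    n_win <- L - k + 1L
    kmers <- substring(seq, seq_len(n_win), seq_len(n_win) + k - 1L)
    cs <- cumsum(c(0, tr[seq_len(L)]))
    win <- cs[(k + 1L):(L + 1L)] - cs[seq_len(n_win)]
    if (window_agg == "abs_sum") win <- abs(win)
    ok <- !grepl("[^ACGT]", kmers)
    tibble::tibble(kmer = kmers[ok], value = win[ok],
                   class = labels[[i]])
  })
  grid <- tidyr::expand_grid(kmer = all_kmers(k), class = lnc_classes())
  summ <- rows |>
    dplyr::group_by(.data$kmer, .data$class) |>
    dplyr::summarise(mean_abs_shap = mean(.data$value),
                     count = dplyr::n(), .groups = "drop")
  grid |>
    dplyr::left_join(summ, by = c("kmer", "class")) |>
    dplyr::mutate(count = dplyr::coalesce(.data$count, 0L)) |>
    dplyr::arrange(.data$class, .data$kmer)
}

#' Export attributions as TSV files
#'
#' Writes one per-nucleotide TSV (`seq_id`, `position`, `nucleotide`,
#' `shap_value`) and one per-frame codon TSV per explained sequence.
#'
#' @param expl A `shap_explanations` object.
#' @param records The records tibble the explanations refer to.
#' @param dir Output directory (created if needed).
#' @return Paths of the written files, invisibly.
#' @export
export_attributions <- function(expl, records, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  records <- as_records(records, need_label = FALSE)
  paths <- character(0)
  nuc <- tidy(expl)
  nuc_wide <- nuc |>
    dplyr::group_by(.data$seq_id, .data$position) |>
    dplyr::summarise(shap_value = sum(.data$shap_value), .groups = "drop")
  nt <- strsplit(stats::setNames(records$seq, records$id), "")
  nuc_wide$nucleotide <- purrr::map2_chr(
    nuc_wide$seq_id, nuc_wide$position, function(id, p) nt[[id]][p])
  p1 <- file.path(dir, "attributions_nucleotide.tsv")
  utils::write.table(
    nuc_wide[, c("seq_id", "position", "nucleotide", "shap_value")],
    p1, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, p1)
  codons <- purrr::map_dfr(expl$explanations, function(e) {
    ct <- codon_aggregate(collapse_to_nucleotide(e)[seq_len(e$length)])
    dplyr::mutate(tidy(ct), seq_id = e$seq_id, .before = 1L)
  })
  p2 <- file.path(dir, "attributions_codon.tsv")
  utils::write.table(codons, p2, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(paths, p2))
}
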