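#' Grid search over hyperparameters
#'
#' Exhaustively trains one model per grid point and scores it on a held-out
#' validation slice (by default 10% of the supplied training records,
#' stratified by class). The winner is the configuration with the highest
#' validation accuracy; ties break deterministically in favour of the first
#' point in lexicographic grid order. Grid points that cannot be built
#' (e.g. kernel wider than the input) are skipped with a warning.
#'
#' @param records A labelled records tibble (the training split).
#' @param grid A named list of candidate values, e.g.
#'   `list(kernel_size = c(9, 15), conv_dropout = c(0.1, 0.3))`. Names must
#'   be [model_config()] arguments.
#' @param base_config A [model_config()] supplying every setting not in the
#'   grid.
#' @param val_fraction Fraction of `records` held out for scoring.
#' @param seed Seed for the validation split; each candidate trains with the
#'   base config seed so runs are comparable and reproducible.
#' @return A list with `best_config` (a `model_config`) and `scores` (a
#'   tibble: one row per grid point with its hyperparameters,
#'   `val_accuracy`, and `status`).
#' @export
grid_search <- function(records, grid, base_config = scaled_model_config(),
                        val_fraction = 0.10, seed = 1L) {
  if (length(grid) == 0L || any(lengths(grid) == 0L)) {
    stop("hyperparameter grid must be non-empty", call. = FALSE)
  }
  stopifnot(val_fraction > 0, val_fraction < 1)
  bad <- setdiff(names(grid), names(formals(model_config)))
  if (length(bad) > 0L) {
    stop("unknown hyperparameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  split <- stratified_split(records, test_fraction = val_fraction,
                            seed = seed)
  points <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
  # lexicographic order over the grid as listed
  points <- points[do.call(order, as.list(points)), , drop = FALSE]
  enc_cache <- new.env(parent = emptyenv())
  scores <- numeric(nrow(points))
  status <- character(nrow(points))
  for (r in seq_len(nrow(points))) {
    overrides <- as.list(points[r, , drop = FALSE])
    config <- try(do.call(model_config,
                          utils::modifyList(unclass(base_config)[
                            names(formals(model_config))], overrides)),
                  silent = TRUE)
    res <- NA_real_
    if (inherits(config, "try-error")) {
      warning("skipping grid point ", r, ": ",
              attr(config, "condition")$message, call. = FALSE)
      status[r] <- "skipped"
    } else {
      res <- try({
        key <- as.character(config$input_length)
        if (is.null(enc_cache[[key]])) {
          enc_cache[[key]] <- list(
            train = encode_dataset(split$train, config$input_length),
            val = encode_dataset(split$test, config$input_length))
        }
        enc <- enc_cache[[key]]
        model <- train_model(build_model(config), enc$train)
        preds <- stats::predict(model, enc$val)
        mean(preds$predicted_label == split$test$label)
      }, silent = TRUE)
      if (inherits(res, "try-error")) {
        warning("skipping grid point ", r, ": ",
                attr(res, "condition")$message, call. = FALSE)
        res <- NA_real_
        status[r] <- "failed"
      } else {
        status[r] <- "ok"
      }
    }
    scores[r] <- res
  }
  if (all(is.na(scores))) {
    stop("no grid point could be trained", call. = FALSE)
  }
  best <- which.max(replace(scores, is.na(scores), -Inf))
  best_config <- do.call(model_config, utils::modifyList(
    unclass(base_config)[names(formals(model_config))],
    as.list(points[best, , drop = FALSE])))
  list(best_config = best_config,
       scores = tibble::as_tibble(cbind(points,
                                        val_accuracy = scores,
                                        status = status)))
}
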