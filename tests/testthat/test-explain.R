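test_that("background selection is balanced, exhaustive-free and seeded", {
  pipe <- pipeline_fixture()
  bg <- select_background(pipe$enc_train, n_per_class = 15L, seed = 4L)
  expect_length(bg$ids, 30L)
  expect_equal(as.integer(table(bg$labels)), c(15L, 15L))
  expect_false(anyDuplicated(bg$ids) > 0)
  bg2 <- select_background(pipe$enc_train, n_per_class = 15L, seed = 4L)
  expect_identical(bg$ids, bg2$ids)
  expect_error(select_background(pipe$enc_train, n_per_class = 1000L),
               "only")
})

test_that("default background draws 175 per class, 350 in total", {
  rr <- recs(paste0("s", 1:700), rep("ACGT", 700),
             rep(c("lncRNA", "mRNA"), 350))
  enc <- encode_dataset(rr, max_len = 8L)
  bg <- select_background(enc, seed = 1L)
  expect_length(bg$ids, 350L)
})

test_that("channel collapse conserves the attribution total exactly", {
  expect_equal(collapse_to_nucleotide(matrix(c(0.1, -0.2, 0.3, 0), 1L)),
               0.2)
  expect_equal(collapse_to_nucleotide(matrix(0, 5L, 4L)), rep(0, 5L))
  withr::with_seed(11, {
    for (i in 1:10) {
      m <- matrix(rnorm(24), 6L, 4L)
      tr <- collapse_to_nucleotide(m)
      # brute-force double loop
      oracle <- vapply(1:6, function(p) sum(m[p, ]), 1)
      expect_equal(tr, oracle)
      expect_equal(sum(tr), sum(m))
    }
  })
})

test_that("codon aggregation reproduces the three-frame arithmetic", {
  ct <- codon_aggregate(c(1, 2, 3, 4, 5, 6))
  expect_equal(ct$frames[["0"]], c(6, 15))
  expect_equal(ct$frames[["1"]], 9)
  expect_equal(ct$frames[["2"]], 12)
  expect_equal(codon_aggregate(rep(0, 10))$frames[["0"]], rep(0, 3))
  expect_error(codon_aggregate(c(1, 2)), "at least 3")
})

test_that("codon aggregation equals a brute-force window oracle", {
  withr::with_seed(12, {
    for (i in 1:10) {
      tr <- rnorm(sample(5:25, 1))
      ct <- codon_aggregate(tr)
      for (f in 0:2) {
        n <- (length(tr) - f) %/% 3
        oracle <- vapply(seq_len(n),
                         function(j) sum(tr[(f + 3 * j - 2):(f + 3 * j)]),
                         1)
        expect_equal(ct$frames[[as.character(f)]], oracle)
        # frame totals match the covered part of the track
        expect_equal(sum(ct$frames[[as.character(f)]]),
                     sum(tr[(f + 1):(f + 3 * n)]))
      }
    }
  })
})

test_that("the conservation chain holds from matrix to codons", {
  pipe <- pipeline_fixture()
  for (e in pipe$expl$explanations[1:5]) {
    track <- collapse_to_nucleotide(e)
    expect_equal(sum(track), sum(e$values))
    ct <- codon_aggregate(track)
    L <- length(track)
    tail0 <- if (L %% 3 == 0) 0 else sum(track[(3 * (L %/% 3) + 1):L])
    expect_equal(sum(ct$frames[["0"]]) + tail0, sum(track))
  }
})

test_that("attribution additivity matches direct model evaluation", {
  pipe <- pipeline_fixture()
  probs <- predict(pipe$model, pipe$enc_test)$p_lncRNA
  for (i in seq_along(pipe$expl$explanations)) {
    e <- pipe$expl$explanations[[i]]
    expect_equal(sum(e$values) + e$base_value, probs[i],
                 tolerance = 1e-6)
  }
})

test_that("explaining a sequence against itself yields zero attribution", {
  pipe <- pipeline_fixture()
  one <- subset_one <- pipe$enc_test
  idx <- 1L
  one <- lnccnn:::subset_encoded(pipe$enc_test, idx)
  expl <- compute_shap(pipe$model, one, one)
  e <- expl$explanations[[1]]
  expect_lt(max(abs(e$values)), 1e-10)
  expect_equal(e$base_value, e$fx, tolerance = 1e-8)
})

test_that("all-zero input against all-zero background attributes nothing", {
  pipe <- pipeline_fixture()
  blank <- encode_dataset(recs("blank", strrep("N", 10L)),
                          max_len = pipe$config$input_length,
                          require_labels = FALSE)
  expl <- compute_shap(pipe$model, blank, blank)
  expect_equal(max(abs(expl$explanations[[1]]$values)), 0)
})

test_that("zero-padded tail positions carry negligible attribution", {
  pipe <- pipeline_fixture()
  for (e in pipe$expl$explanations[1:10]) {
    if (e$length >= nrow(e$values)) next
    pad <- e$values[(e$length + 1L):nrow(e$values), , drop = FALSE]
    expect_lt(max(abs(pad)), 1e-3)
  }
})

test_that("k-mer impact reproduces the worked sliding-window example", {
  tracks <- list(s1 = c(1, 0, 0, 1, 0, 0))
  rr <- recs("s1", "ATGATG", "mRNA")
  ki <- kmer_impact(tracks, rr, k = 3L)
  expect_equal(nrow(ki), 2L * 64L)
  row <- function(km) ki[ki$kmer == km & ki$class == "mRNA", ]
  # every window sum over this track is 1: positions (1,4) carry mass 1
  # and each width-3 window covers exactly one of them
  expect_equal(row("ATG")$mean_abs_shap, 1)
  expect_equal(row("ATG")$count, 2L)
  expect_equal(row("TGA")$mean_abs_shap, 1)
  expect_equal(row("TGA")$count, 1L)
  expect_equal(row("GAT")$mean_abs_shap, 1)
  expect_equal(row("AAA")$count, 0L)
})

test_that("k-mer impact equals a brute-force group-by oracle", {
  withr::with_seed(13, {
    n <- 6L
    rr <- recs(paste0("s", 1:n),
               vapply(1:n, function(i)
                 paste(sample(c("A", "C", "G", "T"), sample(8:20, 1), TRUE),
                       collapse = ""), ""),
               sample(c("lncRNA", "mRNA"), n, TRUE))
    tracks <- lapply(nchar(rr$seq), rnorm)
    names(tracks) <- rr$id
    for (k in 1:3) {
      ki <- kmer_impact(tracks, rr, k = k)
      expect_equal(nrow(ki), 2L * 4L^k)
      # oracle: collect every window by hand
      acc <- list()
      for (i in 1:n) {
        s <- rr$seq[i]; tr <- tracks[[rr$id[i]]]
        for (p in seq_len(nchar(s) - k + 1L)) {
          km <- substr(s, p, p + k - 1L)
          key <- paste(km, rr$label[i])
          acc[[key]] <- c(acc[[key]], abs(sum(tr[p:(p + k - 1L)])))
        }
      }
      for (key in names(acc)) {
        parts <- strsplit(key, " ")[[1]]
        row <- ki[ki$kmer == parts[1] & ki$class == parts[2], ]
        expect_equal(row$mean_abs_shap, mean(acc[[key]]))
        expect_equal(row$count, length(acc[[key]]))
      }
    }
  })
  expect_error(kmer_impact(list(bad = 1:5), recs("s1", "ACGT", "mRNA"), 1L),
               "no attribution track")
})

test_that("all-zero tracks give all-zero impacts", {
  rr <- recs("z", "ACGTACGT", "lncRNA")
  ki <- kmer_impact(list(z = rep(0, 8)), rr, k = 2L)
  present <- ki[ki$count > 0, ]
  expect_true(all(present$mean_abs_shap == 0))
})

test_that("codon-track plots encode sign as the blue/red axis", {
  track <- c(0.5, 0.2, 0.1, 0.4, 0.3, 0.2, 0.6, 0.1, 0.2)
  p_pos <- autoplot(codon_aggregate(track))
  expect_s3_class(p_pos, "ggplot")
  expect_true(all(p_pos$data$value >= 0))
  p_neg <- autoplot(codon_aggregate(-track))
  expect_equal(p_neg$data$value, -p_pos$data$value)
  out <- withr::local_tempfile(fileext = ".png")
  plot_attribution(track, out = out)
  expect_true(file.exists(out))
  expect_gt(file.size(out), 0)
})

test_that("attribution export writes aligned nucleotide and codon tables", {
  pipe <- pipeline_fixture()
  dir <- withr::local_tempdir()
  sub <- lnccnn:::subset_encoded(pipe$enc_test, 1:2)
  expl <- compute_shap(pipe$model, pipe$background, sub)
  rec2 <- pipe$split$test[match(sub$ids, pipe$split$test$id), ]
  export_attributions(expl, rec2, dir)
  nuc <- utils::read.delim(file.path(dir, "attributions_nucleotide.tsv"))
  expect_equal(sort(unique(nuc$seq_id)), sort(sub$ids))
  expect_equal(nrow(nuc), sum(sub$lengths))
  cod <- utils::read.delim(file.path(dir, "attributions_codon.tsv"))
  expect_true(all(cod$frame %in% 0:2))
})
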