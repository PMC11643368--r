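test_that("sequence encoding maps the alphabet and rejects ragged input", {
  m <- encode_sequences(c("ACGTN", "NNNNN"))
  expect_equal(m[1, ], c(0L, 1L, 2L, 3L, 4L))
  expect_true(all(m[2, ] == 4L))
  expect_error(encode_sequences(c("ACGT", "AC")), "same length")
})

grad_check_spec <- function(spec, seed = 2) {
  set.seed(seed)
  X <- matrix(sample(0:4, 4 * spec$input_len, replace = TRUE,
                     prob = c(rep(0.24, 4), 0.04)), 4, spec$input_len)
  y <- c(0, 1, 1, 0)
  w <- ewnscan:::cnn_init_weights(spec$n_kernels, spec$widths, spec$pool,
                                  spec$dense_units, spec$input_len, 7L)
  lg <- ewnscan:::cnn_loss_grad(w, X, y, spec$widths, spec$pool)
  num_grad <- function(get, set) {
    v <- get(w); g <- numeric(length(v)); h <- 1e-6
    for (i in seq_along(v)) {
      vv <- v; vv[i] <- v[i] + h
      lp <- ewnscan:::cnn_loss_grad(set(w, vv), X, y, spec$widths, spec$pool,
                                    FALSE)$loss
      vv[i] <- v[i] - h
      lm <- ewnscan:::cnn_loss_grad(set(w, vv), X, y, spec$widths, spec$pool,
                                    FALSE)$loss
      g[i] <- (lp - lm) / (2 * h)
    }
    g
  }
  gn <- num_grad(function(w) as.numeric(w$conv_W[[1]]),
                 function(w, v) { w$conv_W[[1]][] <- v; w })
  max(abs(gn - as.numeric(lg$grad$conv_W[[1]])))
}

test_that("CNN gradients match central finite differences", {
  spec <- cnn_spec(input_len = 30L, n_kernels = c(3L, 4L), kernel_width = 5L,
                   pool = c(2L, 2L), dense_units = 6L, dropout = 0)
  set.seed(2)
  X <- matrix(sample(0:4, 4 * 30, replace = TRUE,
                     prob = c(rep(0.24, 4), 0.04)), 4, 30)
  y <- c(0, 1, 1, 0)
  w <- ewnscan:::cnn_init_weights(spec$n_kernels, spec$widths, spec$pool,
                                  spec$dense_units, 30L, 7L)
  lg <- ewnscan:::cnn_loss_grad(w, X, y, spec$widths, spec$pool)
  num_grad <- function(get, set) {
    v <- get(w); g <- numeric(length(v)); h <- 1e-6
    for (i in seq_along(v)) {
      vv <- v; vv[i] <- v[i] + h
      lp <- ewnscan:::cnn_loss_grad(set(w, vv), X, y, spec$widths, spec$pool,
                                    FALSE)$loss
      vv[i] <- v[i] - h
      lm <- ewnscan:::cnn_loss_grad(set(w, vv), X, y, spec$widths, spec$pool,
                                    FALSE)$loss
      g[i] <- (lp - lm) / (2 * h)
    }
    g
  }
  pairs <- list(
    list(function(w) as.numeric(w$conv_W[[1]]),
         function(w, v) { w$conv_W[[1]][] <- v; w },
         as.numeric(lg$grad$conv_W[[1]])),
    list(function(w) as.numeric(w$conv_W[[2]]),
         function(w, v) { w$conv_W[[2]][] <- v; w },
         as.numeric(lg$grad$conv_W[[2]])),
    list(function(w) as.numeric(w$W1),
         function(w, v) { w$W1[] <- v; w }, as.numeric(lg$grad$W1)),
    list(function(w) as.numeric(w$W2),
         function(w, v) { w$W2[] <- v; w }, as.numeric(lg$grad$W2)),
    list(function(w) as.numeric(w$conv_b[[1]]),
         function(w, v) { w$conv_b[[1]][] <- v; w },
         as.numeric(lg$grad$conv_b[[1]])))
  for (p in pairs) {
    gn <- num_grad(p[[1]], p[[2]])
    expect_lt(max(abs(gn - p[[3]])), 1e-6)
  }

  # average and global pooling variants backpropagate exactly too
  expect_lt(grad_check_spec(cnn_spec(30L, c(3L, 4L), 5L, c(2L, 0L), 6L,
                                     dropout = 0, pool_type = "avg")), 1e-6)
  expect_lt(grad_check_spec(cnn_spec(30L, 3L, 5L, 0L, 6L, dropout = 0,
                                     pool_type = "max")), 1e-6)
})

test_that("scoring is deterministic, batch-invariant and handles degenerate input", {
  spec <- cnn_spec(input_len = 60L, n_kernels = c(4L, 4L), pool = c(2L, 0L),
                   dense_units = 8L)
  set.seed(3)
  seqs <- random_dna(6, 60)
  sc <- structure(list(weights = ewnscan:::cnn_init_weights(
    spec$n_kernels, spec$widths, spec$pool, spec$dense_units, 60L, 5L),
    spec = spec, seed = 5L), class = "cnn_scorer")
  p1 <- score_sequences(sc, seqs)
  expect_identical(p1, score_sequences(sc, seqs))
  expect_true(all(p1 >= 0 & p1 <= 1))
  # batch composition does not change per-sequence scores
  expect_equal(unname(p1[3]), unname(score_sequences(sc, seqs[3])), tolerance = 1e-12)
  # all-N sequence is scored, not an error
  expect_false(is.na(score_sequences(sc, paste(rep("N", 60), collapse = ""))))
  # wrong length rejected per sequence with ids
  mix <- c(good = seqs[1], bad = "ACGT")
  expect_warning(p <- score_sequences(sc, mix), "bad")
  expect_false(is.na(p["good"]))
  expect_true(is.na(p["bad"]))
  # strand policy: scoring the reverse complement gives the same result
  expect_equal(unname(score_sequences(sc, seqs)),
               unname(score_sequences(sc, ewnscan:::revcomp(seqs))),
               tolerance = 1e-12)
})

test_that("toy motif-count scorer orders sequences by occurrence count", {
  toy <- motif_count_scorer("TGTTTACT", steepness = 2, center = 1)
  bg <- paste(rep("C", 50), collapse = "")
  one <- paste0(substr(bg, 1, 20), "TGTTTACT", substr(bg, 29, 50))
  two <- paste0("TGTTTACT", substr(bg, 9, 40), "TGTTTACT")
  s <- score_sequences(toy, c(bg, one, two))
  expect_true(s[1] < s[2] && s[2] < s[3])
  expect_equal(unname(s[2]), 0.5) # one occurrence sits at the centre
  # reverse-complement occurrences count too
  rc_one <- ewnscan:::revcomp(one)
  expect_equal(unname(score_sequences(toy, rc_one)), unname(s[2]))
})

test_that("threshold calibration honours the target FPR", {
  # direct quantile case: 99 negatives at 0.1, one at 0.9
  negs <- c(rep(0.1, 99), 0.9)
  cal <- suppressWarnings(calibrate_threshold(NULL, negs, fpr = 0.01))
  expect_equal(cal$tau, 0.9)
  expect_lte(cal$empirical_fpr, 0.01)
  # fpr = 1 admits every negative: tau is the minimum score
  cal1 <- suppressWarnings(calibrate_threshold(NULL, negs, fpr = 1))
  expect_equal(cal1$tau, 0.1)
  expect_error(calibrate_threshold(NULL, character(0)), "no negative")
  # unreachable FPR places tau above every negative score
  cal2 <- suppressWarnings(calibrate_threshold(NULL, rep(0.3, 50), fpr = 0.01))
  expect_gt(cal2$tau, 0.3)
  expect_equal(cal2$empirical_fpr, 0)
  # empirical FPR at tau never exceeds the target (property over random draws)
  set.seed(123)
  for (i in 1:20) {
    s <- runif(sample(50:500, 1))
    f <- runif(1, 0.005, 0.2)
    cc <- suppressWarnings(calibrate_threshold(NULL, s, fpr = f))
    expect_lte(cc$empirical_fpr, f)
  }
})

test_that("training separates planted-motif enhancers and collapses on shuffled labels", {
  cfg <- synth_config(seed = 77, seq_len = 200, n_pos = 900, n_neg = 900,
                      motif_set = synthetic_motifs()["FKHD12"])
  es <- generate_enhancer_set(cfg)
  spec <- cnn_spec(input_len = 200L, n_kernels = 16L, kernel_width = 12L,
                   pool = 0L, dense_units = 16L, learning_rate = 2e-3,
                   max_epochs = 25L, patience = 6L, min_epochs = 10L)
  set.seed(7)
  te <- sample(nrow(es$sequences), 600)
  sc <- train_scorer(es$sequences$seq[-te], es$sequences$label[-te], spec,
                     seed = 7L)
  a <- auroc(es$sequences$label[te],
             score_sequences(sc, es$sequences$seq[te]))
  expect_gt(a, 0.85)

  # no-signal control: shuffled labels give chance-level held-out auROC
  # (600 held-out sequences put 3 s.e. of a null auROC at about 0.07)
  set.seed(8)
  ysh <- sample(es$sequences$label)
  sc0 <- train_scorer(es$sequences$seq[-te], ysh[-te], spec, seed = 7L)
  a0 <- auroc(ysh[te], score_sequences(sc0, es$sequences$seq[te]))
  expect_lt(abs(a0 - 0.5), 0.08)

  # determinism: retraining with the same seed reproduces the weights
  sc2 <- train_scorer(es$sequences$seq[-te], es$sequences$label[-te], spec,
                      seed = 7L)
  expect_identical(sc$weights, sc2$weights)

  expect_error(train_scorer(es$sequences$seq[1:5], rep(1, 5), spec),
               "single class")
})

test_that("held-out auROC does not decrease with motif information content", {
  base <- synthetic_motifs(conc = 0.95)["FKHD12"]
  aucs <- vapply(c(0.35, 0.65, 1.0), function(alpha) {
    motif <- list(FKHD12 = pwm_soften(base[[1]], alpha))
    cfg <- synth_config(seed = 88, seq_len = 150, n_pos = 400, n_neg = 400,
                        motif_set = motif)
    es <- generate_enhancer_set(cfg)
    spec <- cnn_spec(input_len = 150L, n_kernels = 12L, kernel_width = 12L,
                     pool = 0L, dense_units = 12L, learning_rate = 2e-3,
                     max_epochs = 20L, patience = 5L, min_epochs = 10L)
    set.seed(9)
    te <- sample(nrow(es$sequences), 200)
    sc <- train_scorer(es$sequences$seq[-te], es$sequences$label[-te], spec,
                       seed = 9L)
    auroc(es$sequences$label[te], score_sequences(sc, es$sequences$seq[te]))
  }, numeric(1))
  expect_true(all(diff(aucs) > -0.02)) # monotone up to seed noise
})

test_that("scorer survives a plain-text round trip", {
  spec <- cnn_spec(input_len = 40L, n_kernels = 4L, pool = 2L, dense_units = 4L)
  sc <- structure(list(weights = ewnscan:::cnn_init_weights(
    spec$n_kernels, spec$widths, spec$pool, spec$dense_units, 40L, 3L),
    spec = spec, seed = 3L), class = "cnn_scorer")
  seqs <- random_dna(4, 40)
  f <- tempfile(fileext = ".json")
  write_scorer(sc, f, calibration = structure(
    list(tau = 0.5, fpr = 0.01, empirical_fpr = 0.009, n_negatives = 1000L),
    class = "calibration"))
  sc2 <- read_scorer(f)
  expect_equal(score_sequences(sc2, seqs), score_sequences(sc, seqs),
               tolerance = 1e-12)
  expect_equal(attr(sc2, "calibration")$tau, 0.5)
})

test_that("training-set construction merges, excludes promoters and splits", {
  set.seed(10)
  genome <- list(chr1 = paste(sample(c("A", "C", "G", "T"), 60000, TRUE),
                              collapse = ""))
  h3k <- data.frame(chrom = "chr1", start = c(5000, 20000), end = c(9000, 24000))
  dhs <- data.frame(chrom = "chr1",
                    start = c(5500, 7600, 21000, 40000),
                    end = c(6500, 8600, 22000, 41000))
  bg <- data.frame(chrom = "chr1", start = seq(30000, 38000, by = 2000),
                   end = seq(30600, 38600, by = 2000))
  ts <- build_training_set(h3k, dhs, bg, genome, length_bp = 1000,
                           include_rc = FALSE, seed = 4)
  # two DHS peaks inside the first H3K27ac peak merge into one positive
  expect_equal(sum(ts$label == 1), 2L)
  expect_true(all(nchar(ts$seq) == 1000))
  expect_true(all(ts$split %in% c("train", "validation", "test")))

  # a promoter window removes the overlapping candidate
  prom <- data.frame(chrom = "chr1", start = 21500, end = 21500)
  ts2 <- build_training_set(h3k, dhs, bg, genome, promoters = prom,
                            length_bp = 1000, include_rc = FALSE, seed = 4)
  expect_equal(sum(ts2$label == 1), 1L)

  # empty DHS input: no positives, no error
  ts3 <- build_training_set(h3k, dhs[0, ], bg, genome, length_bp = 1000,
                            include_rc = FALSE, seed = 4)
  expect_equal(sum(ts3$label == 1), 0L)

  # reverse complements are appended for positives
  ts4 <- build_training_set(h3k, dhs, bg, genome, length_bp = 1000,
                            include_rc = TRUE, seed = 4)
  expect_equal(sum(ts4$label == 1), 4L)

  # interval off the chromosome end is dropped and counted
  h3k_edge <- data.frame(chrom = "chr1", start = 59500, end = 60000)
  dhs_edge <- data.frame(chrom = "chr1", start = 59600, end = 59900)
  ts5 <- build_training_set(h3k_edge, dhs_edge, bg, genome, length_bp = 1000,
                            include_rc = FALSE, seed = 4)
  expect_equal(sum(ts5$label == 1), 0L)
  expect_gte(attr(ts5, "n_dropped_offend"), 1L)
})
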