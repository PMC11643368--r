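test_that("PWM construction validates and summarises matrices", {
  m <- pwm_from_consensus("TGTTTACT", conc = 0.85)
  expect_equal(colSums(m$mat), rep(1, 8), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(pwm_consensus(m), "TGTTTACT")
  expect_true(pwm_information_content(m) > 8)
  expect_gt(pwm_information_content(m),
            pwm_information_content(pwm_soften(m, 0.5)))
  bad <- matrix(0.3, 4, 6)
  expect_error(pwm(bad))
})

test_that("log-odds scanning matches the naive per-position oracle", {
  set.seed(21)
  worst <- 0
  for (i in 1:100) {
    w <- sample(4:12, 1)
    mat <- matrix(rexp(4 * w), 4)
    mat <- sweep(mat, 2, colSums(mat), "/")
    p <- pwm(mat, id = "r")
    seq <- random_dna(1, sample(30:80, 1))
    got <- pwm_score_positions(p, seq)
    want <- pwm_score_oracle(mat, rep(0.25, 4), 0.01, seq)
    worst <- max(worst, max(abs(got - want)))
  }
  expect_lt(worst, 1e-9)
  # N positions can never be hits
  pN <- pwm_from_consensus("ACGT")
  expect_equal(pwm_score_positions(pN, "NNACGT"),
               c(-Inf, -Inf, pwm_score_positions(pN, "ACGT")))
})

test_that("threshold calibration bounds the background hit density", {
  set.seed(22)
  m <- pwm_from_consensus("TGTTTACTTAGC", conc = 0.9)
  bg <- random_dna(20, 1000)
  cal <- calibrate_motif_threshold(m, bg, fp_per_10kb = 5)
  expect_lte(cal$calibration$hit_density_per_10kb, 5)
  # held-out background stays near the calibrated density
  held <- random_dna(20, 1000)
  held_hits <- sum(ewnscan:::pwm_scores_both(cal, held) >= cal$threshold)
  expect_lte(held_hits / sum(nchar(held)) * 1e4, 5 * 2)

  # monotone: a stricter FP budget never lowers the threshold
  thr <- vapply(c(50, 5, 1, 0), function(fp)
    calibrate_motif_threshold(m, bg, fp)$threshold, numeric(1))
  expect_true(all(diff(thr) >= 0))

  # fp_per_10kb = 0 sits strictly above the best background score
  t0 <- calibrate_motif_threshold(m, bg, 0)
  expect_gt(t0$threshold, max(ewnscan:::pwm_scores_both(m, bg)))

  # all-A background vs a motif needing G everywhere: no hits at any cutoff
  g <- pwm_from_consensus("GGGGGG", conc = 0.99)
  calA <- calibrate_motif_threshold(g, strrep("A", 10000), fp_per_10kb = 5)
  expect_equal(calA$calibration$background_hits, 0L, ignore_attr = TRUE)

  # planted consensus every 100 bp: threshold must clear near-consensus scores
  planted <- strrep("A", 10000)
  for (st in seq(1, 9901, by = 100))
    substr(planted, st, st + 11) <- "TGTTTACTTAGC"
  calP <- calibrate_motif_threshold(m, planted, fp_per_10kb = 5)
  cons_score <- max(pwm_score_positions(m, "TGTTTACTTAGC"))
  expect_gt(calP$threshold, cons_score)
})

test_that("dinucleotide shuffling preserves dinucleotide counts", {
  set.seed(23)
  s <- random_dna(1, 300, gc = 0.6)
  sh <- shuffle_dinucleotides(s, seed = 5)
  dinucs <- function(x) {
    b <- strsplit(x, "")[[1]]
    table(paste0(b[-length(b)], b[-1]))
  }
  expect_identical(dinucs(s), dinucs(sh))
  expect_false(identical(s, sh))
  expect_identical(shuffle_dinucleotides(s, seed = 5),
                   shuffle_dinucleotides(s, seed = 5))
})

test_that("allele-aware scanning applies the either-allele rule in the window", {
  mg <- make_motif_genome(n_snps = 3)
  m <- pwm_from_consensus(mg$consensus, conc = 0.9)
  set.seed(24)
  m <- calibrate_motif_threshold(m, random_dna(20, 1000), fp_per_10kb = 1)
  hits <- scan_alleles(m, mg$panel, mg$genome, flank = 50)
  # alt allele completes the consensus: counted under the either-allele rule
  expect_true(all(hits$has_hit))
  expect_true(all(hits$n_hits_alt >= 1))

  # a SNP far from any motif has no hit under either allele
  far <- data.frame(snp_id = "far", chrom = "chr1", pos = 1500L,
                    ref = substr(mg$genome$chr1, 1500, 1500), alt = "A")
  far$alt <- setdiff(c("A", "C", "G", "T"), far$ref)[1]
  expect_false(scan_alleles(m, far, mg$genome)$has_hit)

  # a motif just outside the 100-bp window is not counted
  snp_near <- mg$panel[1, ]
  shifted <- data.frame(snp_id = "sh", chrom = "chr1",
                        pos = snp_near$pos + 80L, ref = NA, alt = NA)
  shifted$ref <- substr(mg$genome$chr1, shifted$pos, shifted$pos)
  shifted$alt <- setdiff(c("A", "C", "G", "T"), shifted$ref)[1]
  # window [pos-50, pos+49] ends 30+ bp before the broken motif completes;
  # the broken motif alone must not reach the calibrated threshold
  expect_false(scan_alleles(m, shifted, mg$genome)$has_hit)

  # strand symmetry: hit counts are invariant under reverse complement
  g2 <- list(chr1 = ewnscan:::revcomp(mg$genome$chr1))
  L <- nchar(mg$genome$chr1)
  flipped <- mg$panel
  flipped$pos <- L - mg$panel$pos + 1L
  flipped$ref <- ewnscan:::revcomp(mg$panel$ref)
  flipped$alt <- ewnscan:::revcomp(mg$panel$alt)
  hits_rc <- scan_alleles(m, flipped, g2, flank = 50)
  expect_equal(hits_rc$n_hits_ref + hits_rc$n_hits_alt,
               hits$n_hits_ref + hits$n_hits_alt)
})

test_that("motif enrichment reproduces the 2x2 oracle and labelling gates", {
  hits_fg <- list(M1 = rep(c(TRUE, FALSE), c(40, 60)),
                  M2 = rep(c(TRUE, FALSE), c(10, 90)))
  hits_bg <- list(M1 = rep(c(TRUE, FALSE), c(100, 900)),
                  M2 = rep(c(TRUE, FALSE), c(100, 900)))
  res <- motif_enrichment(hits_fg, hits_bg)
  expect_equal(res$odds_ratio[res$motif_id == "M1"], (40 * 900) / (60 * 100),
               tolerance = 1e-12)
  expect_equal(res$occurrence_fg[1], 0.4)
  # equal rates: OR 1 and p >= 0.5 under the one-sided test
  expect_equal(res$odds_ratio[res$motif_id == "M2"], 1)
  expect_gte(res$p_value[res$motif_id == "M2"], 0.5)
  expect_true(all(res$q_value >= res$p_value - 1e-12))

  ewn_calls <- data.frame(snp_id = sprintf("s%d", 1:100),
                          ewn = rep(c(9L, 3L), c(40, 60)))
  esnps <- data.frame(snp_id = sprintf("s%d", 1:100), chrom = "chr1",
                      pos = seq(1000, by = 500, length.out = 100))
  genes <- data.frame(gene_id = sprintf("g%d", 1:30), chrom = "chr1",
                      start = seq(500, by = 1200, length.out = 30),
                      end = seq(1300, by = 1200, length.out = 30),
                      strand = "+")
  res2 <- motif_enrichment(hits_fg, hits_bg, ewn_calls = ewn_calls,
                           esnps = esnps, genes = genes)
  r1 <- res2[res2$motif_id == "M1", ]
  expect_equal(r1$mean_ewn, 9)
  expect_gte(r1$n_target_genes, 15)
  expect_true(r1$labelled)
})

test_that("nearest-gene assignment ranks by TSS distance with strand awareness", {
  genes <- data.frame(gene_id = c("g1", "g2", "g3"), chrom = "chr1",
                      start = c(9000, 15000, 60000),
                      end = c(11000, 16000, 62000),
                      strand = c("+", "-", "+"))
  # TSSs: g1 at 9000, g2 at 16000 (minus strand), g3 at 60000
  nn <- nearest_genes("chr1", 10000, genes)
  expect_equal(nn$gene_id, c("g1", "g2"))
  expect_equal(nn$distance, c(1000, 6000))
  expect_false(attr(nn, "short"))
  # single-gene chromosome: short list flagged
  one <- nearest_genes("chr1", 10000, genes[1, , drop = FALSE])
  expect_equal(nrow(one), 1L)
  expect_true(attr(one, "short"))
})

test_that("MEME round trip preserves matrices and scanning behaviour", {
  motifs <- synthetic_motifs()
  f <- tempfile(fileext = ".meme")
  write_meme(motifs, f)
  back <- read_meme(f)
  expect_setequal(names(back), names(motifs))
  for (id in names(motifs)) {
    expect_equal(back[[id]]$mat, motifs[[id]]$mat, tolerance = 1e-5)
    s <- random_dna(1, 60)
    expect_equal(pwm_score_positions(back[[id]], s),
                 pwm_score_positions(motifs[[id]], s), tolerance = 1e-4)
  }
})
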