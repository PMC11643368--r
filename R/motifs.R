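#' Position weight matrix
#'
#' A PWM is stored as a 4 x w probability matrix (rows A, C, G, T; columns
#' sum to 1) together with its log-odds form against a background base
#' composition, computed with a pseudocount, and an optional calibrated hit
#' threshold (see [calibrate_motif_threshold()]).
#'
#' @param mat 4 x w numeric matrix of base probabilities (rows A,C,G,T).
#' @param id motif identifier.
#' @param background base composition of the null model (length-4, sums to 1).
#' @param pseudocount added to probabilities before taking log-odds.
#' @return an object of class `pwm`.
#' @export
pwm <- function(mat, id = "motif", background = rep(0.25, 4),
                pseudocount = 0.01) {
  mat <- as.matrix(mat)
  stopifnot(nrow(mat) == 4L, ncol(mat) >= 4L,
            all(abs(colSums(mat) - 1) < 1e-6), all(mat >= 0))
  rownames(mat) <- c("A", "C", "G", "T")
  background <- background / sum(background)
  lo <- log2((mat + pseudocount) / (1 + 4 * pseudocount)) -
    log2(matrix(background, 4, ncol(mat)))
  rownames(lo) <- rownames(mat)
  structure(list(id = id, mat = mat, log_odds = lo, background = background,
                 pseudocount = pseudocount, threshold = NULL),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("PWM", x$id, "(", ncol(x$mat), "bp,",
      sprintf("%.1f", pwm_information_content(x)), "bits ) consensus",
      pwm_consensus(x),
      if (!is.null(x$threshold)) sprintf("; threshold %.3f", x$threshold),
      "\n")
  invisible(x)
}

#' @rdname pwm
#' @param consensus consensus string for [pwm_from_consensus()].
#' @param conc probability mass on the consensus base per column.
#' @export
pwm_from_consensus <- function(consensus, id = consensus, conc = 0.85,
                               background = rep(0.25, 4)) {
  bases <- strsplit(toupper(consensus), "")[[1]]
  stopifnot(all(bases %in% c("A", "C", "G", "T")))
  mat <- matrix((1 - conc) / 3, nrow = 4, ncol = length(bases),
                dimnames = list(c("A", "C", "G", "T"), NULL))
  mat[cbind(match(bases, rownames(mat)), seq_along(bases))] <- conc
  pwm(mat, id = id, background = background)
}

#' @rdname pwm
#' @param x a `pwm`.
#' @export
pwm_consensus <- function(x) {
  paste(rownames(x$mat)[apply(x$mat, 2, which.max)], collapse = "")
}

#' @rdname pwm
#' @export
pwm_sample <- function(x) {
  paste(apply(x$mat, 2, function(p) sample(rownames(x$mat), 1L, prob = p)),
        collapse = "")
}

#' @rdname pwm
#' @details `pwm_information_content()` is the total information content in
#'   bits against a uniform background; `pwm_soften()` mixes the matrix with
#'   the uniform distribution (`alpha = 1` leaves it unchanged, `alpha = 0`
#'   is uninformative), used to generate motif-strength series.
#' @export
pwm_information_content <- function(x) {
  p <- x$mat
  sum(apply(p, 2, function(col) {
    col <- col[col > 0]
    2 + sum(col * log2(col))
  }))
}

#' @rdname pwm
#' @param alpha mixing weight of the original matrix in [pwm_soften()].
#' @export
pwm_soften <- function(x, alpha) {
  stopifnot(alpha >= 0, alpha <= 1)
  pwm(alpha * x$mat + (1 - alpha) * 0.25, id = x$id,
      background = x$background, pseudocount = x$pseudocount)
}

#' Log-odds PWM scores at every start position
#'
#' Scores a single strand: position j gets the sum of per-column log-odds of
#' the bases at j .. j+w-1. Positions containing a non-ACGT base score -Inf
#' (they can never be hits).
#'
#' @param x a [pwm()].
#' @param seq a DNA string.
#' @return numeric vector of length `nchar(seq) - w + 1` (empty if the
#'   sequence is shorter than the motif).
#' @export
pwm_score_positions <- function(x, seq) {
  w <- ncol(x$mat)
  L <- nchar(seq)
  if (L < w) return(numeric(0))
  codes <- match(strsplit(toupper(seq), "")[[1]], rownames(x$mat))
  n <- L - w + 1L
  scores <- numeric(n)
  bad <- logical(n)
  for (k in seq_len(w)) {
    ck <- codes[k:(k + n - 1L)]
    miss <- is.na(ck)
    bad <- bad | miss
    ck[miss] <- 1L
    scores <- scores + x$log_odds[cbind(ck, k)]
  }
  scores[bad] <- -Inf
  scores
}

# all scores over both strands of a set of sequences (used for calibration
# and hit counting); reverse-strand scores are computed on the reverse
# complement so hit counts are strand-symmetric by construction
pwm_scores_both <- function(x, seqs) {
  unlist(lapply(seqs, function(s)
    c(pwm_score_positions(x, s), pwm_score_positions(x, revcomp(s)))),
    use.names = FALSE)
}

#' Calibrate a per-motif hit threshold at a target false-positive density
#'
#' Scans the motif over background sequences (both strands) and returns the
#' smallest log-odds threshold whose background hit density does not exceed
#' `fp_per_10kb` hits per 10 kb of sequence. With `fp_per_10kb = 0` the
#' threshold is placed strictly above the best background score.
#'
#' @param x a [pwm()].
#' @param background_sequences character vector of background DNA (e.g.
#'   dinucleotide-shuffled genomic sequence, see [shuffle_dinucleotides()]).
#' @param fp_per_10kb allowed false positives per 10 kb (default 5).
#' @return the `pwm` with `$threshold` set (and `$calibration` diagnostics).
#' @export
calibrate_motif_threshold <- function(x, background_sequences,
                                      fp_per_10kb = 5) {
  stopifnot(inherits(x, "pwm"), length(background_sequences) > 0,
            fp_per_10kb >= 0)
  total_bp <- sum(nchar(background_sequences))
  scores <- pwm_scores_both(x, background_sequences)
  scores <- scores[is.finite(scores)]
  allowed <- fp_per_10kb * total_bp / 1e4
  if (length(scores) == 0L) {
    thr <- min(x$log_odds[x$log_odds > -Inf]) # nothing scoreable: floor
  } else {
    s <- sort(scores)
    first <- which(!duplicated(s))
    cand <- s[first]
    n_ge <- length(s) - first + 1 # hits at threshold = each candidate score
    ok <- which(n_ge <= allowed)
    thr <- if (length(ok)) cand[ok[1L]] else max(s) + 1e-9
  }
  x$threshold <- thr
  hits <- if (length(scores)) sum(scores >= thr) else 0L
  x$calibration <- list(fp_per_10kb = fp_per_10kb, background_bp = total_bp,
                        background_hits = hits,
                        hit_density_per_10kb = hits / total_bp * 1e4)
  x
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Altschul-Erickson shuffle: permutes a sequence while preserving its exact
#' dinucleotide counts, by shuffling the outgoing edge lists of the
#' dinucleotide multigraph and checking that the induced last-edge tree
#' connects to the terminal base (rejection otherwise).
#'
#' @param seq a DNA string.
#' @param seed optional integer seed.
#' @return shuffled string with identical dinucleotide composition.
#' @export
shuffle_dinucleotides <- function(seq, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  s <- strsplit(toupper(seq), "")[[1]]
  n <- length(s)
  if (n <= 2L) return(seq)
  first <- s[1L]
  last <- s[n]
  edges <- split(s[-1L], factor(s[-n], levels = unique(s)))
  edges <- edges[lengths(edges) > 0L]
  repeat {
    sh <- lapply(edges, function(e) if (length(e) > 1L) sample(e) else e)
    # Eulerian-path validity: from every used vertex except the terminal one,
    # the *last* outgoing edge must lead (transitively) to the terminal base
    lastE <- vapply(sh, function(e) e[length(e)], character(1))
    ok <- TRUE
    for (v in names(sh)) {
      if (v == last) next
      cur <- v
      seen <- character(0)
      repeat {
        if (cur == last) break
        if (cur %in% seen || !cur %in% names(lastE)) { ok <- FALSE; break }
        seen <- c(seen, cur)
        cur <- lastE[[cur]]
      }
      if (!ok) break
    }
    if (ok) break
  }
  ptr <- setNames(rep(1L, length(sh)), names(sh))
  out <- character(n)
  out[1L] <- first
  cur <- first
  for (i in 2L:n) {
    nxt <- sh[[cur]][ptr[[cur]]]
    ptr[[cur]] <- ptr[[cur]] + 1L
    out[i] <- nxt
    cur <- nxt
  }
  paste(out, collapse = "")
}

#' Scan both alleles of SNP-centred windows for motif hits
#'
#' For each SNP, the window of `2*flank` bp centred on it is built twice --
#' once with the reference and once with the alternate base -- and both
#' strands of both versions are scanned. A SNP carries the motif when either
#' allele version has at least one hit at or above the calibrated threshold,
#' which avoids allelic bias in downstream enrichment.
#'
#' @param x a calibrated [pwm()] (threshold set).
#' @param esnps data.frame with columns chrom, pos (1-based), ref, alt,
#'   snp_id.
#' @param genome named list / `DNAStringSet` of chromosome sequences.
#' @param flank half-width of the scanned window (default 50, i.e. 100 bp).
#' @return data.frame: snp_id, n_hits_ref, n_hits_alt, has_hit.
#' @export
scan_alleles <- function(x, esnps, genome, flank = 50L) {
  stopifnot(inherits(x, "pwm"))
  if (is.null(x$threshold)) stop("PWM has no calibrated threshold")
  genome <- as_genome(genome)
  count_hits <- function(s)
    sum(pwm_score_positions(x, s) >= x$threshold) +
    sum(pwm_score_positions(x, revcomp(s)) >= x$threshold)
  n <- NROW(esnps)
  n_ref <- integer(n); n_alt <- integer(n)
  for (i in seq_len(n)) {
    chrom_seq <- genome[[esnps$chrom[i]]]
    pos <- esnps$pos[i]
    start <- max(1L, pos - flank)
    end <- min(nchar(chrom_seq), pos + flank - 1L)
    win <- substr(chrom_seq, start, end)
    off <- pos - start + 1L
    if (toupper(substr(win, off, off)) != toupper(esnps$ref[i]))
      stop("reference allele mismatch at ", esnps$snp_id[i])
    alt_win <- win
    substr(alt_win, off, off) <- toupper(esnps$alt[i])
    n_ref[i] <- count_hits(win)
    n_alt[i] <- count_hits(alt_win)
  }
  data.frame(snp_id = esnps$snp_id, n_hits_ref = n_ref, n_hits_alt = n_alt,
             has_hit = n_ref + n_alt > 0L, stringsAsFactors = FALSE)
}

#' Motif enrichment of eSNPs over background SNPs
#'
#' One-sided Fisher's exact test (enrichment) on the 2x2 table of
#' motif-carrying vs motif-free SNPs in the foreground (eSNPs) and background
#' (non-eSNPs), per motif; presence/absence per SNP, occurrences normalised
#' by set size. Benjamini-Hochberg q-values are added across motifs. When
#' eSNP calls and a gene annotation are supplied, the per-TF summary gains
#' the mean EWN of motif-carrying eSNPs and the number of distinct target
#' genes under the two-nearest-genes rule, plus the reporting flag used for
#' figure labelling (targets >= 15 and mean EWN >= 7).
#'
#' @param hits_fg named list (per motif id) of logical vectors: which
#'   foreground SNPs carry the motif (e.g. `scan_alleles()$has_hit`).
#' @param hits_bg same structure for the background set.
#' @param ewn_calls optional data.frame with snp_id, ewn for the foreground
#'   SNPs (rows aligned with `hits_fg` vectors).
#' @param esnps optional foreground SNP table (chrom, pos, snp_id) for target
#'   gene counting.
#' @param genes optional gene annotation (see [nearest_genes()]).
#' @param label_min_targets,label_min_ewn reporting gates.
#' @return data.frame, one row per motif: counts, normalised occurrence,
#'   odds ratio, p, q, and (if computable) mean_ewn, n_target_genes, labelled.
#' @export
motif_enrichment <- function(hits_fg, hits_bg, ewn_calls = NULL, esnps = NULL,
                             genes = NULL, label_min_targets = 15L,
                             label_min_ewn = 7) {
  stopifnot(identical(names(hits_fg), names(hits_bg)))
  rows <- lapply(names(hits_fg), function(id) {
    fg <- hits_fg[[id]]; bg <- hits_bg[[id]]
    a <- sum(fg); b <- length(fg) - a
    c_ <- sum(bg); d <- length(bg) - c_
    p <- fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE),
                     alternative = "greater")$p.value
    or <- (a * d) / (b * c_) # unconditional sample odds ratio
    out <- data.frame(motif_id = id, n_fg = a, total_fg = length(fg),
                      n_bg = c_, total_bg = length(bg),
                      occurrence_fg = a / length(fg),
                      occurrence_bg = c_ / length(bg),
                      odds_ratio = or, p_value = p, stringsAsFactors = FALSE)
    if (!is.null(ewn_calls))
      out$mean_ewn <- if (a > 0) mean(ewn_calls$ewn[fg]) else NA_real_
    if (!is.null(esnps) && !is.null(genes)) {
      hit_snps <- esnps[fg, , drop = FALSE]
      targets <- unique(unlist(lapply(seq_len(NROW(hit_snps)), function(i)
        nearest_genes(hit_snps$chrom[i], hit_snps$pos[i], genes)$gene_id)))
      out$n_target_genes <- length(targets)
    }
    out
  })
  res <- do.call(rbind, rows)
  res$q_value <- p.adjust(res$p_value, method = "BH")
  if (!is.null(res$mean_ewn) && !is.null(res$n_target_genes))
    res$labelled <- !is.na(res$mean_ewn) &
      res$n_target_genes >= label_min_targets & res$mean_ewn >= label_min_ewn
  res
}

#' k nearest genes by TSS distance
#'
#' Gene position is the strand-aware transcription start site. The `k` genes
#' on the SNP's chromosome with the smallest absolute TSS distance are
#' returned, ties broken by genomic order. If fewer than `k` genes exist on
#' the chromosome the short list is flagged.
#'
#' @param chrom,pos SNP location (1-based).
#' @param genes data.frame with gene_id, chrom, start, end, strand; or a
#'   `GRanges` with a `gene_id` column.
#' @param k number of genes (default 2, the two-nearest-genes rule).
#' @return data.frame: gene_id, tss, distance, with attribute `short` when
#'   fewer than `k` genes were available.
#' @export
nearest_genes <- function(chrom, pos, genes, k = 2L) {
  if (methods::is(genes, "GRanges"))
    genes <- data.frame(
      gene_id = S4Vectors::mcols(genes)$gene_id,
      chrom = as.character(GenomicRanges::seqnames(genes)),
      start = GenomicRanges::start(genes), end = GenomicRanges::end(genes),
      strand = as.character(GenomicRanges::strand(genes)),
      stringsAsFactors = FALSE)
  g <- genes[genes$chrom == chrom, , drop = FALSE]
  tss <- ifelse(g$strand == "-", g$end, g$start)
  ord <- order(abs(tss - pos), tss)
  take <- utils::head(ord, k)
  out <- data.frame(gene_id = g$gene_id[take], tss = tss[take],
                    distance = abs(tss - pos)[take], stringsAsFactors = FALSE)
  attr(out, "short") <- nrow(out) < k
  out
}

#' Read motifs from a minimal MEME-format file
#'
#' Parses the minimal MEME motif format (as exported by JASPAR): a
#' `MOTIF <id> [name]` line followed by a `letter-probability matrix:` block
#' of w rows with 4 columns in A,C,G,T order.
#'
#' @param path file path.
#' @param background,pseudocount forwarded to [pwm()].
#' @return named list of [pwm()] objects.
#' @export
read_meme <- function(path, background = rep(0.25, 4), pseudocount = 0.01) {
  lines <- readLines(path, warn = FALSE)
  motif_at <- grep("^MOTIF\\b", lines)
  if (length(motif_at) == 0L) stop("no MOTIF blocks in ", path)
  out <- list()
  for (i in seq_along(motif_at)) {
    hdr <- strsplit(trimws(lines[motif_at[i]]), "\\s+")[[1]]
    id <- hdr[2]
    lpm <- grep("letter-probability matrix", lines)
    lpm <- lpm[lpm > motif_at[i]][1]
    if (is.na(lpm)) stop("motif ", id, ": missing letter-probability matrix")
    stop_at <- if (i < length(motif_at)) motif_at[i + 1] - 1L else length(lines)
    block <- lines[(lpm + 1L):stop_at]
    rows <- lapply(block, function(ln) {
      flds <- suppressWarnings(as.numeric(strsplit(trimws(ln), "\\s+")[[1]]))
      if (length(flds) == 4L && !anyNA(flds)) flds else NULL
    })
    rows <- Filter(Negate(is.null), rows)
    if (length(rows) < 4L) stop("motif ", id, ": matrix too short")
    mat <- t(do.call(rbind, rows)) # rows become columns: 4 x w, A,C,G,T
    mat <- apply(mat, 2, function(col) col / sum(col))
    out[[id]] <- pwm(mat, id = id, background = background,
                     pseudocount = pseudocount)
  }
  out
}

#' Write motifs to a minimal MEME-format file
#' @param motifs named list of [pwm()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_meme <- function(motifs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               "A 0.25 C 0.25 G 0.25 T 0.25", ""), con)
  for (m in motifs) {
    writeLines(sprintf("MOTIF %s", m$id), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
      ncol(m$mat)), con)
    for (j in seq_len(ncol(m$mat)))
      writeLines(paste(sprintf("%.6f", m$mat[, j]), collapse = " "), con)
    writeLines("", con)
  }
  invisible(path)
}
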