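#' Build an enhancer training set from peak intervals and a genome
#'
#' Positives are DNase-hypersensitive (DHS) peaks that overlap an active
#' histone mark (H3K27ac) peak: DHS peaks falling inside the same H3K27ac
#' peak are merged into one, each merged peak is re-centred and extended to
#' the model input length, and any candidate overlapping a promoter window
#' (TSS +/- `promoter_flank`) is removed. Negatives are the supplied
#' background DHS regions (pan-tissue open chromatin) that do not overlap
#' any positive, likewise re-centred and extended, subsampled to
#' `neg_ratio` negatives per positive. Reverse complements of the positives
#' are appended within each split. Intervals extending past a chromosome end
#' are dropped and counted.
#'
#' @param h3k27ac,dhs `GRanges` (or data.frame chrom/start/end, 1-based
#'   inclusive) of active-mark and open-chromatin peaks.
#' @param background_dhs `GRanges`/data.frame of negative-control open
#'   regions.
#' @param promoters optional `GRanges`/data.frame of TSS positions (width-1
#'   ranges or intervals); each is expanded by `promoter_flank` on both
#'   sides.
#' @param genome genome sequences (named character / `DNAStringSet`).
#' @param length_bp output sequence length (default 1000).
#' @param promoter_flank promoter half-width in bp (default 1000).
#' @param neg_ratio negatives per positive (default 10, configurable; use 1
#'   for balanced sets).
#' @param split train/validation/test fractions (default 0.70/0.15/0.15).
#' @param include_rc append reverse complements of positives per split.
#' @param seed controls the split and negative subsampling.
#' @return data.frame: id, seq, label (1 = enhancer), split; attribute
#'   `n_dropped_offend` counts intervals lost at chromosome ends.
#' @export
build_training_set <- function(h3k27ac, dhs, background_dhs, genome,
                               promoters = NULL, length_bp = 1000L,
                               promoter_flank = 1000L, neg_ratio = 1L,
                               split = c(train = 0.70, validation = 0.15,
                                         test = 0.15),
                               include_rc = TRUE, seed = 1L) {
  genome <- as_genome(genome)
  h3k27ac <- as_granges(h3k27ac)
  dhs <- as_granges(dhs)
  background_dhs <- as_granges(background_dhs)
  stopifnot(abs(sum(split) - 1) < 1e-8)

  # DHS peaks inside the same H3K27ac peak are merged into one
  ov <- GenomicRanges::findOverlaps(dhs, h3k27ac)
  pos <- GenomicRanges::GRanges()
  if (length(ov) > 0L) {
    by_peak <- split(S4Vectors::queryHits(ov), S4Vectors::subjectHits(ov))
    merged <- lapply(by_peak, function(ix)
      GenomicRanges::reduce(GenomicRanges::GRanges(
        GenomicRanges::seqnames(dhs)[ix],
        IRanges::IRanges(min(GenomicRanges::start(dhs)[ix]),
                         max(GenomicRanges::end(dhs)[ix])))))
    pos <- unique(do.call(c, unname(merged)))
  }
  pos <- recenter(pos, length_bp)
  if (!is.null(promoters) && length(pos) > 0L) {
    prom <- as_granges(promoters)
    prom <- GenomicRanges::resize(prom,
                                  GenomicRanges::width(prom) + 2L * promoter_flank,
                                  fix = "center")
    pos <- pos[GenomicRanges::countOverlaps(pos, prom) == 0L]
  }
  neg <- recenter(background_dhs, length_bp)
  if (length(pos) > 0L)
    neg <- neg[GenomicRanges::countOverlaps(neg, pos) == 0L]

  n_dropped <- 0L
  fetch <- function(gr, prefix) {
    if (length(gr) == 0L)
      return(data.frame(id = character(0), seq = character(0)))
    chrom <- as.character(GenomicRanges::seqnames(gr))
    lens <- vapply(genome[chrom], nchar, 1L)
    ok <- GenomicRanges::start(gr) >= 1L & GenomicRanges::end(gr) <= lens
    n_dropped <<- n_dropped + sum(!ok)
    gr <- gr[ok]; chrom <- chrom[ok]
    seqs <- vapply(seq_along(gr), function(i)
      substr(genome[[chrom[i]]], GenomicRanges::start(gr)[i],
             GenomicRanges::end(gr)[i]), character(1))
    data.frame(id = sprintf("%s_%d", prefix, seq_along(seqs)), seq = seqs,
               stringsAsFactors = FALSE)
  }
  pos_df <- fetch(pos, "enh")
  neg_df <- fetch(neg, "bg")

  set.seed(seed)
  if (nrow(pos_df) > 0L && nrow(neg_df) > neg_ratio * nrow(pos_df))
    neg_df <- neg_df[sample.int(nrow(neg_df), neg_ratio * nrow(pos_df)), ,
                     drop = FALSE]

  assign_split <- function(n) {
    if (n == 0L) return(character(0))
    sample(rep(names(split), diff(round(cumsum(c(0, split)) * n))))
  }
  pos_df$label <- rep(1L, nrow(pos_df))
  neg_df$label <- rep(0L, nrow(neg_df))
  pos_df$split <- assign_split(nrow(pos_df))
  neg_df$split <- assign_split(nrow(neg_df))
  out <- rbind(pos_df, neg_df)
  if (include_rc && nrow(pos_df) > 0L) {
    rc <- pos_df
    rc$id <- paste0(rc$id, "_rc")
    rc$seq <- revcomp(rc$seq)
    out <- rbind(out, rc)
  }
  rownames(out) <- NULL
  attr(out, "n_dropped_offend") <- n_dropped
  out
}

as_granges <- function(x) {
  if (methods::is(x, "GRanges")) return(x)
  if (is.data.frame(x)) {
    gr <- GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$start, x$end))
    if (!is.null(x$strand)) GenomicRanges::strand(gr) <- x$strand
    return(gr)
  }
  stop("expected a GRanges or a chrom/start/end data.frame")
}

recenter <- function(gr, length_bp) {
  if (length(gr) == 0L) return(gr)
  GenomicRanges::resize(gr, length_bp, fix = "center")
}
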