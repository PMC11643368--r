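#' Hudson-style FST from two population allele frequencies
#'
#' Population-level estimator `(p1 - p2)^2 / (p1 (1 - p2) + p2 (1 - p1))`,
#' clamped to \[0, 1\] and defined as 0 when both populations are fixed for
#' the same allele (0/0 denominator). No sample-size correction is applied:
#' only population frequencies, not genotype counts, flow through the
#' pipeline.
#'
#' @param p1,p2 allele frequencies in \[0, 1\] (vectorised).
#' @return FST values in \[0, 1\].
#' @export
fst_hudson <- function(p1, p2) {
  if (any(p1 < 0 | p1 > 1 | p2 < 0 | p2 > 1, na.rm = TRUE))
    stop("allele frequencies must lie in [0, 1]")
  num <- (p1 - p2)^2
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  out <- ifelse(den == 0, 0, num / den)
  pmin(pmax(out, 0), 1)
}

#' Filter a SNP panel to common non-coding variants
#'
#' Keeps SNPs whose minor allele frequency is at least `maf` in either
#' population, and drops SNPs falling inside annotated coding (CDS)
#' intervals. SNPs with missing frequencies are dropped and counted in the
#' `n_missing_af` attribute.
#'
#' @param panel data.frame with chrom, pos, af_aa, af_ea.
#' @param cds optional CDS intervals: a `GRanges`, or a data.frame with
#'   chrom, start, end (1-based inclusive).
#' @param maf minor-allele-frequency floor (default 0.05).
#' @return the filtered panel.
#' @export
filter_common_noncoding <- function(panel, cds = NULL, maf = 0.05) {
  miss <- is.na(panel$af_aa) | is.na(panel$af_ea)
  if (any(miss))
    message("dropping ", sum(miss), " SNP(s) with missing allele frequency")
  panel <- panel[!miss, , drop = FALSE]
  minor_aa <- pmin(panel$af_aa, 1 - panel$af_aa)
  minor_ea <- pmin(panel$af_ea, 1 - panel$af_ea)
  panel <- panel[minor_aa >= maf | minor_ea >= maf, , drop = FALSE]
  if (!is.null(cds) && nrow(panel) > 0L) {
    if (!methods::is(cds, "GRanges"))
      cds <- GenomicRanges::GRanges(cds$chrom,
                                    IRanges::IRanges(cds$start, cds$end))
    snp_gr <- GenomicRanges::GRanges(panel$chrom,
                                     IRanges::IRanges(panel$pos, panel$pos))
    hits <- GenomicRanges::countOverlaps(snp_gr, cds) > 0L
    panel <- panel[!hits, , drop = FALSE]
  }
  out <- panel
  attr(out, "n_missing_af") <- sum(miss)
  out
}

#' Retain the top FST quantile of a panel
#'
#' Keeps the SNPs whose FST is at least the value of the
#' `ceiling(quantile * n)`-th largest FST; ties at the cutoff are all
#' retained, so with distinct values exactly `ceiling(quantile * n)` SNPs
#' survive.
#'
#' @param panel data.frame with an `fst` column.
#' @param quantile upper tail fraction to keep (default 0.05).
#' @return the filtered panel.
#' @export
select_top_fst <- function(panel, quantile = 0.05) {
  stopifnot(quantile > 0, quantile <= 1, !is.null(panel$fst))
  n <- nrow(panel)
  if (n == 0L) return(panel)
  k <- ceiling(quantile * n)
  cutoff <- sort(panel$fst, decreasing = TRUE)[k]
  out <- panel[panel$fst >= cutoff, , drop = FALSE]
  attr(out, "fst_cutoff") <- cutoff
  out
}

#' Assign ancestry dominance of the alternate allele
#'
#' `AA` when the alternate-allele frequency is higher in the
#' African-ancestry population, `EA` when higher in the European-ancestry
#' population, `tie` when equal. Tied SNPs are excluded from both
#' dominance-stratified downstream sets.
#'
#' @param panel data.frame with af_aa, af_ea.
#' @return the panel with a `dominance` column.
#' @export
assign_dominance <- function(panel) {
  panel$dominance <- ifelse(panel$af_aa > panel$af_ea, "AA",
                            ifelse(panel$af_ea > panel$af_aa, "EA", "tie"))
  panel
}

#' Enrichment-ratio curve of foreground over background scores
#'
#' For each cutoff c the ratio of the fraction of foreground scores
#' exceeding c to the fraction of background scores exceeding c (e.g. GWAS
#' z-scores of eSNPs vs non-eSNPs). Cutoffs where the background fraction is
#' zero give `NA`. Optional bootstrap CIs resample the foreground.
#'
#' @param fg_scores,bg_scores numeric score vectors.
#' @param cutoffs numeric cutoffs.
#' @param n_boot bootstrap replicates for the CI (0 = none).
#' @param conf CI level.
#' @param seed seed for the bootstrap.
#' @return data.frame: cutoff, frac_fg, frac_bg, ratio (and ci_lo, ci_hi
#'   when bootstrapped).
#' @export
enrichment_ratio_curve <- function(fg_scores, bg_scores, cutoffs,
                                   n_boot = 0L, conf = 0.95, seed = 1L) {
  frac_fg <- vapply(cutoffs, function(c) mean(fg_scores > c), numeric(1))
  frac_bg <- vapply(cutoffs, function(c) mean(bg_scores > c), numeric(1))
  ratio <- ifelse(frac_bg > 0, frac_fg / frac_bg, NA_real_)
  out <- data.frame(cutoff = cutoffs, frac_fg = frac_fg, frac_bg = frac_bg,
                    ratio = ratio)
  if (n_boot > 0L) {
    set.seed(seed)
    boots <- replicate(n_boot, {
      fg <- sample(fg_scores, replace = TRUE)
      vapply(cutoffs, function(c)
        if (frac_bg[match(c, cutoffs)] > 0)
          mean(fg > c) / frac_bg[match(c, cutoffs)] else NA_real_,
        numeric(1))
    })
    boots <- matrix(boots, nrow = length(cutoffs))
    a <- (1 - conf) / 2
    out$ci_lo <- apply(boots, 1, stats::quantile, probs = a, na.rm = TRUE)
    out$ci_hi <- apply(boots, 1, stats::quantile, probs = 1 - a, na.rm = TRUE)
  }
  out
}
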