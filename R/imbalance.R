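#' Call allelic imbalance at heterozygous sites
#'
#' Tests merged ref/alt read counts at heterozygous sites of gained and lost
#' eSNPs. Sites with fewer than `min_reads` total reads are excluded (no
#' verdict). For the remaining sites a one-sided exact binomial test of the
#' favoured allele's count against p = 0.5 is combined with a read-ratio
#' gate: a gained-direction site is imbalanced when `alt/ref > ratio` and
#' the binomial P is at most `alpha`; a lost-direction site mirrors this
#' with `ref/alt`. A zero denominator with a non-zero numerator counts as an
#' infinite ratio (passes the gate).
#'
#' @param sites data.frame with snp_id, ref_reads, alt_reads, direction
#'   (`gained` or `lost`; the model-predicted direction being tested).
#' @param min_reads minimum total reads for a verdict (default 6).
#' @param ratio directional read-ratio gate (default 1.5).
#' @param alpha binomial p-value gate (default 0.01).
#' @return the input with total, ratio, p_value, excluded and imbalanced
#'   columns filled. Excluded sites have `NA` verdicts.
#' @export
call_imbalance <- function(sites, min_reads = 6L, ratio = 1.5, alpha = 0.01) {
  stopifnot(all(c("ref_reads", "alt_reads", "direction") %in% names(sites)),
            all(sites$direction %in% c("gained", "lost")),
            all(sites$ref_reads >= 0), all(sites$alt_reads >= 0))
  total <- sites$ref_reads + sites$alt_reads
  favoured <- ifelse(sites$direction == "gained", sites$alt_reads,
                     sites$ref_reads)
  other <- total - favoured
  # one-sided exact binomial upper tail: P(X >= favoured | n = total, 0.5)
  p <- pbinom(favoured - 1, total, 0.5, lower.tail = FALSE)
  rat <- ifelse(other == 0, ifelse(favoured > 0, Inf, NaN), favoured / other)
  excluded <- total < min_reads
  sites$total <- total
  sites$ratio <- ifelse(excluded, NA_real_, rat)
  sites$p_value <- ifelse(excluded, NA_real_, p)
  sites$excluded <- excluded
  sites$imbalanced <- ifelse(excluded, NA,
                             !is.nan(rat) & rat > ratio & p <= alpha)
  sites
}

#' Compare allelic-imbalance fractions between two site sets
#'
#' Fractions of imbalanced sites (over sites with a verdict) in a foreground
#' set (eSNPs) and a background set (non-eSNPs), the sample odds ratio, and
#' a two-sided Fisher exact p-value on the 2x2 imbalanced/not table.
#'
#' @param calls_fg,calls_bg outputs of [call_imbalance()].
#' @return list: frac_fg, frac_bg, odds_ratio, p_value, table (the 2x2).
#' @export
compare_fractions <- function(calls_fg, calls_bg) {
  fg <- calls_fg$imbalanced[!calls_fg$excluded]
  bg <- calls_bg$imbalanced[!calls_bg$excluded]
  if (length(bg) == 0L) stop("no background sites with a verdict")
  if (length(fg) == 0L) stop("no foreground sites with a verdict")
  a <- sum(fg); b <- length(fg) - a
  c_ <- sum(bg); d <- length(bg) - c_
  tab <- matrix(c(a, b, c_, d), nrow = 2, byrow = TRUE,
                dimnames = list(c("fg", "bg"), c("imbalanced", "balanced")))
  list(frac_fg = a / length(fg), frac_bg = c_ / length(bg),
       odds_ratio = (a * d) / (b * c_),
       p_value = fisher.test(tab)$p.value, table = tab)
}
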