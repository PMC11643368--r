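# Independent brute-force oracles. These deliberately share no code with the
# package implementations they check.

# naive re-statement of the essential-window-number rule
ewn_oracle <- function(ref_scores, alt_scores, tau, min_ewn = 5,
                       consistency = 0.85) {
  n <- length(ref_scores)
  n_act <- 0L
  n_deact <- 0L
  n_pos <- 0L
  n_neg <- 0L
  for (i in seq_len(n)) {
    d <- alt_scores[i] - ref_scores[i]
    if (d > 0) n_pos <- n_pos + 1L
    if (d < 0) n_neg <- n_neg + 1L
    if (ref_scores[i] < tau && alt_scores[i] >= tau) n_act <- n_act + 1L
    if (alt_scores[i] < tau && ref_scores[i] >= tau) n_deact <- n_deact + 1L
  }
  if (n_pos / n > consistency && n_act >= min_ewn)
    list(direction = "gained", ewn = n_act)
  else if (n_neg / n > consistency && n_deact >= min_ewn)
    list(direction = "lost", ewn = n_deact)
  else
    list(direction = "none", ewn = max(n_act, n_deact))
}

# exact upper-tail binomial probability as a plain density sum
binom_tail_oracle <- function(k, n, p = 0.5) {
  if (k > n) return(0)
  sum(dbinom(k:n, n, p))
}

# per-position PWM log-odds score by explicit double loop
pwm_score_oracle <- function(mat, background, pseudocount, seq) {
  lo <- log2((mat + pseudocount) / (1 + 4 * pseudocount)) -
    log2(matrix(background / sum(background), 4, ncol(mat)))
  bases <- strsplit(toupper(seq), "")[[1]]
  w <- ncol(mat)
  out <- numeric(length(bases) - w + 1)
  for (j in seq_along(out)) {
    s <- 0
    for (k in seq_len(w)) {
      r <- match(bases[j + k - 1], c("A", "C", "G", "T"))
      if (is.na(r)) { s <- -Inf; break }
      s <- s + lo[r, k]
    }
    out[j] <- s
  }
  out
}

fst_oracle <- function(p1, p2) {
  num <- (p1 - p2)^2
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  if (den == 0) return(0)
  min(max(num / den, 0), 1)
}

# 2x2 Fisher p-value as an explicit hypergeometric sum (two-sided)
fisher_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

random_dna <- function(n, len, gc = 0.5) {
  probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, TRUE, prob = probs),
          collapse = ""), character(1))
}

# single-chromosome toy genome with SNP sites whose alt allele completes a
# planted motif: at each site the consensus is planted with one base changed
# to the ref allele, so substituting the alt allele restores the full motif
make_motif_genome <- function(n_snps = 5, gap = 3000L, consensus = "TGTTTACTTAGC",
                              mut_at = 4L, seed = 99L) {
  set.seed(seed)
  w <- nchar(consensus)
  total <- gap * (n_snps + 1L)
  chrom <- paste(sample(c("A", "C", "G", "T"), total, TRUE), collapse = "")
  alt_base <- substr(consensus, mut_at, mut_at)
  ref_base <- setdiff(c("A", "C", "G", "T"), alt_base)[1]
  broken <- consensus
  substr(broken, mut_at, mut_at) <- ref_base
  pos <- integer(n_snps)
  for (i in seq_len(n_snps)) {
    start <- gap * i
    substr(chrom, start, start + w - 1L) <- broken
    pos[i] <- start + mut_at - 1L
  }
  list(genome = list(chr1 = chrom),
       panel = data.frame(snp_id = sprintf("esnp_%d", seq_len(n_snps)),
                          chrom = "chr1", pos = pos, ref = ref_base,
                          alt = alt_base, stringsAsFactors = FALSE),
       consensus = consensus)
}
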