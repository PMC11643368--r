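#' Encode DNA sequences as an integer code matrix
#'
#' Maps A,C,G,T to codes 0--3; any other letter (N, IUPAC ambiguity) maps to 4
#' and is one-hot encoded as an all-zero column by the model.
#'
#' @param seqs character vector of equal-length DNA strings.
#' @return integer matrix, one row per sequence.
#' @keywords internal
encode_sequences <- function(seqs) {
  if (length(seqs) == 0L) return(matrix(integer(0), nrow = 0L, ncol = 0L))
  L <- unique(nchar(seqs))
  if (length(L) != 1L)
    stop("sequences must all have the same length")
  lut <- rep(4L, 127L)
  lut[utf8ToInt("A")] <- 0L; lut[utf8ToInt("a")] <- 0L
  lut[utf8ToInt("C")] <- 1L; lut[utf8ToInt("c")] <- 1L
  lut[utf8ToInt("G")] <- 2L; lut[utf8ToInt("g")] <- 2L
  lut[utf8ToInt("T")] <- 3L; lut[utf8ToInt("t")] <- 3L
  codes <- lut[utf8ToInt(paste(seqs, collapse = ""))]
  matrix(codes, nrow = length(seqs), ncol = L, byrow = TRUE)
}

#' Reverse complement of character DNA sequences
#' @param seqs character vector.
#' @return character vector.
#' @keywords internal
revcomp <- function(seqs) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs)))
}

#' Score sequences with an enhancer-activity scorer
#'
#' Generic entry point of the scorer contract: every scorer maps equal-length
#' DNA sequences to activity scores in \[0, 1\], higher meaning more
#' enhancer-like. The default strand policy scores the forward strand and the
#' reverse complement and averages the two, which makes scoring
#' strand-symmetric regardless of how the scorer was trained.
#'
#' Sequences whose length does not match the scorer's expected input length
#' are rejected individually: their score is `NA` and a warning names them.
#'
#' @param scorer a scorer object (`cnn_scorer` or `motif_count_scorer`).
#' @param seqs character vector of DNA sequences (optionally named; names are
#'   used in per-sequence rejection messages).
#' @param strand `"both"` (mean of forward and reverse-complement scores,
#'   default) or `"forward"`.
#' @return numeric vector of scores in \[0, 1\], same length as `seqs`.
#' @export
score_sequences <- function(scorer, seqs, strand = c("both", "forward")) {
  UseMethod("score_sequences")
}

#' @export
score_sequences.default <- function(scorer, seqs, strand = c("both", "forward")) {
  stop("no score_sequences() method for class ", paste(class(scorer), collapse = "/"))
}

check_lengths <- function(seqs, L) {
  ok <- nchar(seqs) == L
  if (!all(ok)) {
    ids <- names(seqs)[!ok]
    if (is.null(ids) || all(!nzchar(ids))) ids <- which(!ok)
    warning("rejected ", sum(!ok), " sequence(s) with length != ", L, ": ",
            paste(utils::head(ids, 10L), collapse = ", "))
  }
  ok
}

#' Toy motif-count scorer
#'
#' A deterministic scorer used to exercise the sliding-window machinery
#' independently of any trained model: the score of a sequence is a logistic
#' function of the number of exact occurrences of a consensus string on
#' either strand, `plogis(steepness * (count - center))`.
#'
#' With the default `center = 1`, a motif-free sequence scores
#' `plogis(-steepness)` (inactive) and a single planted occurrence scores 0.5,
#' so an activation threshold of 0.5 separates them.
#'
#' @param consensus consensus string (A/C/G/T).
#' @param steepness logistic slope per motif occurrence.
#' @param center occurrence count at which the score crosses 0.5.
#' @return an object of class `motif_count_scorer`.
#' @export
motif_count_scorer <- function(consensus, steepness = 2, center = 1) {
  stopifnot(nchar(consensus) >= 1L, grepl("^[ACGT]+$", consensus))
  structure(list(consensus = toupper(consensus), steepness = steepness,
                 center = center),
            class = "motif_count_scorer")
}

#' @export
score_sequences.motif_count_scorer <- function(scorer, seqs,
                                               strand = c("both", "forward")) {
  strand <- match.arg(strand)
  if (length(seqs) == 0L) return(numeric(0))
  # occurrence counting already covers both strands; the strand policy is a
  # no-op here because the count (hence the score) is strand-symmetric
  dss <- Biostrings::DNAStringSet(toupper(seqs))
  n_fwd <- Biostrings::vcountPattern(scorer$consensus, dss)
  n_rev <- Biostrings::vcountPattern(revcomp(scorer$consensus), dss)
  stats::plogis(scorer$steepness * (n_fwd + n_rev - scorer$center))
}

#' Calibrate the activation threshold at a target false-positive rate
#'
#' Scores a set of negative (non-enhancer) sequences and returns the smallest
#' threshold tau such that the empirical fraction of negatives scoring
#' `>= tau` does not exceed the target FPR; ties at the cutoff are broken
#' upward. A sequence is called an active enhancer when its score is `>= tau`.
#'
#' @param scorer a scorer object (ignored when `negatives` is numeric).
#' @param negatives character vector of negative sequences, or a numeric
#'   vector of already-computed negative scores.
#' @param fpr target false-positive rate (default 0.01).
#' @param strand strand policy passed to [score_sequences()].
#' @return an object of class `calibration`: list with `tau`, `fpr`
#'   (the target), `empirical_fpr`, and `n_negatives`.
#' @export
calibrate_threshold <- function(scorer, negatives, fpr = 0.01,
                                strand = c("both", "forward")) {
  strand <- match.arg(strand)
  if (length(negatives) == 0L) stop("no negative sequences supplied")
  stopifnot(fpr > 0, fpr <= 1)
  if (length(negatives) < 100 / fpr)
    warning("only ", length(negatives), " negatives for FPR ", fpr,
            "; at least ", ceiling(100 / fpr), " recommended")
  scores <- if (is.numeric(negatives)) negatives else
    score_sequences(scorer, negatives, strand = strand)
  scores <- scores[!is.na(scores)]
  n <- length(scores)
  s <- sort(scores)
  first <- which(!duplicated(s))
  cand <- s[first]
  # number of scores >= cand[i] is the tail starting at its first occurrence
  frac_ge <- (n - first + 1) / n
  ok <- which(frac_ge <= fpr)
  tau <- if (length(ok)) cand[ok[1L]] else max(scores) + 1e-9
  structure(list(tau = tau, fpr = fpr,
                 empirical_fpr = mean(scores >= tau),
                 n_negatives = n),
            class = "calibration")
}

#' @export
print.calibration <- function(x, ...) {
  cat("Activation threshold calibration\n")
  cat(sprintf("  tau = %.6g (target FPR %.4g, empirical %.4g on %d negatives)\n",
              x$tau, x$fpr, x$empirical_fpr, x$n_negatives))
  invisible(x)
}
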