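#' Coerce a genome to a named character list
#'
#' Accepts a `Biostrings::DNAStringSet`, a named character vector, or a named
#' list of strings, and returns a named character list keyed by chromosome.
#' @param genome the genome in any accepted form.
#' @return named list of chromosome strings.
#' @keywords internal
as_genome <- function(genome) {
  if (methods::is(genome, "DNAStringSet"))
    genome <- as.character(genome)
  if (is.character(genome)) genome <- as.list(genome)
  if (is.null(names(genome)) || any(!nzchar(names(genome))))
    stop("genome sequences must be named by chromosome")
  genome
}

#' Enumerate sliding windows overlapping a SNP
#'
#' Places candidate enhancer windows of length `window_len` with centres at
#' every `stride` bp within `+/- region` bp of the SNP; every window contains
#' the SNP. At the defaults (1000-bp windows, stride 20, region 200) this
#' yields 21 windows. Windows that would extend past either end of the
#' chromosome are dropped and the reduced count is recorded.
#'
#' @param snp_pos 1-based SNP position.
#' @param window_len window length in bp (the model input length).
#' @param stride centre spacing in bp.
#' @param region maximum |centre - SNP| offset in bp; must be a multiple of
#'   `stride`.
#' @param seq_len chromosome length, if known, to drop off-end windows.
#' @return data.frame: start, end (1-based inclusive), center_offset
#'   (centre minus SNP position), snp_offset (1-based SNP position within the
#'   window); attribute `n_dropped` counts windows lost to sequence ends.
#' @export
enumerate_windows <- function(snp_pos, window_len = 1000L, stride = 20L,
                              region = 200L, seq_len = NULL) {
  stopifnot(region >= 0L, stride >= 1L, region %% stride == 0L,
            window_len >= 1L, region < window_len / 2)
  offs <- seq.int(-region, region, by = stride)
  center0 <- (snp_pos - 1L) + offs              # 0-based centre
  start0 <- center0 - window_len %/% 2L         # 0-based half-open internally
  start <- start0 + 1L
  end <- start0 + window_len
  keep <- start >= 1L
  if (!is.null(seq_len)) keep <- keep & end <= seq_len
  out <- data.frame(start = start[keep], end = end[keep],
                    center_offset = offs[keep],
                    snp_offset = snp_pos - start[keep] + 1L)
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Per-window allele scores and delta profile of a SNP
#'
#' For each sliding window overlapping the SNP, the window sequence is
#' extracted, the SNP base is set to the reference and to the alternate
#' allele, both versions are scored under the scorer's strand policy, and
#' the per-window delta (alt minus ref) is recorded. The reference allele
#' must match the genome base at the SNP position; indels are rejected.
#'
#' @param scorer a scorer object (see [score_sequences()]).
#' @param genome genome sequences (named by chromosome).
#' @param snp one-row data.frame (or list) with chrom, pos, ref, alt and
#'   optionally snp_id.
#' @param window_len,stride,region window geometry, see
#'   [enumerate_windows()].
#' @param strand strand policy forwarded to the scorer.
#' @return an object of class `delta_profile`: data.frame with
#'   center_offset, ref_score, alt_score, delta, plus attributes `snp_id`
#'   and `n_dropped`.
#' @export
delta_profile <- function(scorer, genome, snp, window_len = 1000L,
                          stride = 20L, region = 200L,
                          strand = c("both", "forward")) {
  strand <- match.arg(strand)
  genome <- as_genome(genome)
  snp_id <- if (!is.null(snp$snp_id)) snp$snp_id else
    paste0(snp$chrom, ":", snp$pos)
  ref <- toupper(snp$ref); alt <- toupper(snp$alt)
  if (nchar(ref) != 1L || nchar(alt) != 1L)
    stop(snp_id, ": only single-nucleotide variants are supported")
  chrom_seq <- genome[[snp$chrom]]
  if (is.null(chrom_seq)) stop(snp_id, ": chromosome ", snp$chrom, " not in genome")
  genome_base <- toupper(substr(chrom_seq, snp$pos, snp$pos))
  if (genome_base != ref)
    stop(snp_id, ": reference allele ", ref, " does not match genome base ",
         genome_base, " at ", snp$chrom, ":", snp$pos)
  win <- enumerate_windows(snp$pos, window_len = window_len, stride = stride,
                           region = region, seq_len = nchar(chrom_seq))
  if (nrow(win) == 0L) stop(snp_id, ": no complete windows on the chromosome")
  ref_seqs <- character(nrow(win)); alt_seqs <- character(nrow(win))
  for (i in seq_len(nrow(win))) {
    s <- substr(chrom_seq, win$start[i], win$end[i])
    substr(s, win$snp_offset[i], win$snp_offset[i]) <- ref
    ref_seqs[i] <- s
    substr(s, win$snp_offset[i], win$snp_offset[i]) <- alt
    alt_seqs[i] <- s
  }
  scores <- score_sequences(scorer, c(ref_seqs, alt_seqs), strand = strand)
  n <- nrow(win)
  out <- data.frame(center_offset = win$center_offset,
                    ref_score = scores[seq_len(n)],
                    alt_score = scores[n + seq_len(n)])
  out$delta <- out$alt_score - out$ref_score
  structure(out, class = c("delta_profile", "data.frame"),
            snp_id = snp_id, n_dropped = attr(win, "n_dropped"))
}

#' Essential window number and gained/lost classification
#'
#' Counts activation windows (ref score below the activation threshold tau,
#' alt score at or above it) and deactivation windows (the reverse). A SNP is
#' called `gained` when more than `consistency` of its windows have positive
#' delta and at least `min_ewn` windows are activated; `lost` mirrors this
#' with negative deltas and deactivation; otherwise `none`. The EWN is the
#' activation count for gained calls, the deactivation count for lost calls,
#' and the larger of the two (reported for diagnostics) for `none`. Zero
#' deltas count as sign-inconsistent for both directions.
#'
#' @param profile a [delta_profile()] (any data.frame with ref_score,
#'   alt_score, delta works).
#' @param tau activation threshold, or a `calibration` object.
#' @param min_ewn minimum essential windows to call a direction (default 5).
#' @param consistency required fraction of same-sign deltas, strict
#'   inequality (default 0.85).
#' @return one-row data.frame: snp_id, n_windows, ewn, direction,
#'   consistent_fraction, n_activation, n_deactivation.
#' @export
compute_ewn <- function(profile, tau, min_ewn = 5L, consistency = 0.85) {
  if (inherits(tau, "calibration")) tau <- tau$tau
  n <- nrow(profile)
  stopifnot(n >= 1L)
  n_act <- sum(profile$ref_score < tau & profile$alt_score >= tau)
  n_deact <- sum(profile$alt_score < tau & profile$ref_score >= tau)
  frac_pos <- sum(profile$delta > 0) / n
  frac_neg <- sum(profile$delta < 0) / n
  if (frac_pos > consistency && n_act >= min_ewn) {
    direction <- "gained"; ewn <- n_act; cf <- frac_pos
  } else if (frac_neg > consistency && n_deact >= min_ewn) {
    direction <- "lost"; ewn <- n_deact; cf <- frac_neg
  } else {
    direction <- "none"; ewn <- max(n_act, n_deact); cf <- max(frac_pos, frac_neg)
  }
  data.frame(snp_id = attr(profile, "snp_id") %||% NA_character_,
             n_windows = n, ewn = as.integer(ewn), direction = direction,
             consistent_fraction = cf, n_activation = as.integer(n_act),
             n_deactivation = as.integer(n_deact), stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Scan a SNP panel for gained/lost enhancer-activity variants
#'
#' Applies [delta_profile()] and [compute_ewn()] to every SNP in the panel.
#' Per-SNP failures (reference mismatches, indels, SNPs without complete
#' windows) are collected and the scan continues; the failed SNPs are
#' reported in the `errors` attribute and a gained/lost/none summary in the
#' `summary` attribute.
#'
#' @inheritParams delta_profile
#' @param tau activation threshold or `calibration` object.
#' @param panel data.frame with chrom, pos, ref, alt and optionally snp_id.
#' @param min_ewn,consistency forwarded to [compute_ewn()].
#' @return data.frame of [compute_ewn()] rows, one per scanned SNP.
#' @export
scan_panel <- function(scorer, tau, genome, panel, window_len = 1000L,
                       stride = 20L, region = 200L, min_ewn = 5L,
                       consistency = 0.85, strand = c("both", "forward")) {
  strand <- match.arg(strand)
  genome <- as_genome(genome)
  calls <- vector("list", NROW(panel))
  errors <- character(0)
  for (i in seq_len(NROW(panel))) {
    snp <- panel[i, , drop = FALSE]
    res <- tryCatch({
      prof <- delta_profile(scorer, genome, snp, window_len = window_len,
                            stride = stride, region = region, strand = strand)
      compute_ewn(prof, tau, min_ewn = min_ewn, consistency = consistency)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors <- c(errors, conditionMessage(res))
    } else {
      calls[[i]] <- res
    }
  }
  out <- do.call(rbind, calls)
  if (is.null(out))
    out <- data.frame(snp_id = character(0), n_windows = integer(0),
                      ewn = integer(0), direction = character(0),
                      consistent_fraction = numeric(0),
                      n_activation = integer(0), n_deactivation = integer(0),
                      stringsAsFactors = FALSE)
  attr(out, "errors") <- errors
  attr(out, "summary") <- c(gained = sum(out$direction == "gained"),
                            lost = sum(out$direction == "lost"),
                            none = sum(out$direction == "none"),
                            failed = length(errors))
  out
}
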