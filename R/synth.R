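#' Configuration of the synthetic-data generators
#'
#' One seeded configuration drives every generator, so a full synthetic study
#' (planted-motif enhancer sequences, a two-population SNP panel on an FST
#' continuum, allelic read counts, and case/control genotypes) is reproduced
#' bit-identically from `(config, seed)`. Each generator draws from its own
#' sub-stream derived from the global seed, so regenerating one input never
#' perturbs the others.
#'
#' Defaults emulate the study conditions the pipeline is designed for:
#' 1-kb enhancer windows, human-like background GC of 0.41, a Balding-Nichols
#' two-population allele-frequency model (more post-bottleneck drift in the
#' European- than the African-ancestry population), negative-binomial ChIP
#' read depths, and a logistic liability model for case/control status.
#'
#' @param seed integer master seed.
#' @param seq_len sequence length in bp (must match the model input length).
#' @param n_pos,n_neg number of enhancer / background sequences.
#' @param gc background GC content (default 0.41, human-like).
#' @param motif_set named list of [pwm()] objects planted into positives.
#' @param n_instances candidate numbers of planted instances per positive
#'   (one value is drawn uniformly per sequence).
#' @param plant `"sample"` draws each instance from the PWM; `"consensus"`
#'   plants the exact consensus string.
#' @param include_rc append reverse complements of the positives.
#' @param fst_params list: `n_snps`, `anc_range` (ancestral-frequency range),
#'   drift parameters `c_aa`, `c_ea` in \[0, 1) (the Balding-Nichols FST of
#'   each population against the ancestral pool).
#' @param readcount_params list: `depth` (mean), `depth_size` (negative
#'   binomial dispersion; ignored for `depth_dist = "fixed"`), `depth_dist`
#'   (`"nbinom"` or `"fixed"`), `effect` (allelic log-odds at true eSNPs).
#' @param genotype_params list: `n_individuals`, `n_causal`, `weight_scale`
#'   (s.d. of true risk weights), `case_fraction` (target case rate, hit by
#'   bisection of the liability intercept), `population` (`"EA"` or `"AA"`:
#'   which allele-frequency column drives Hardy-Weinberg dosages).
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(seed = 1L, seq_len = 1000L, n_pos = 100L,
                         n_neg = 100L, gc = 0.41,
                         motif_set = synthetic_motifs(),
                         n_instances = 1:3, plant = c("sample", "consensus"),
                         include_rc = FALSE,
                         fst_params = list(n_snps = 1000L,
                                           anc_range = c(0.05, 0.95),
                                           c_aa = 0.05, c_ea = 0.10),
                         readcount_params = list(depth = 30, depth_size = 5,
                                                 depth_dist = "nbinom",
                                                 effect = 2),
                         genotype_params = list(n_individuals = 2000L,
                                                n_causal = 10L,
                                                weight_scale = 0.5,
                                                case_fraction = 0.5,
                                                population = "EA")) {
  plant <- match.arg(plant)
  stopifnot(length(motif_set) >= 1L, gc > 0, gc < 1,
            seq_len >= max(vapply(motif_set, function(m) ncol(m$mat), 1L)))
  stopifnot(fst_params$c_aa >= 0, fst_params$c_aa < 1,
            fst_params$c_ea >= 0, fst_params$c_ea < 1)
  structure(list(seed = as.integer(seed), seq_len = as.integer(seq_len),
                 n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 gc = gc, motif_set = motif_set, n_instances = n_instances,
                 plant = plant, include_rc = include_rc,
                 fst_params = fst_params,
                 readcount_params = readcount_params,
                 genotype_params = genotype_params),
            class = "synth_config")
}

# independent RNG sub-stream per generator, kept below 2^31
substream_seed <- function(seed, what) {
  off <- c(enhancers = 101L, panel = 211L, readcounts = 307L,
           genotypes = 401L, genome = 503L)[[what]]
  as.integer((as.numeric(seed) * 7919 + off * 104729) %% 2147483647)
}

#' Built-in synthetic transcription-factor motifs
#'
#' Three PWMs used as planted signal: a 12-bp forkhead-like motif, a 9-bp
#' homeodomain-like motif and an 8-bp E-box-like motif. Columns put
#' probability `conc` on the consensus base, so information content scales
#' with `conc` (about 1.15 bits/column at the default 0.85).
#'
#' @param conc per-column probability of the consensus base.
#' @return named list of [pwm()] objects.
#' @export
synthetic_motifs <- function(conc = 0.85) {
  list(FKHD12 = pwm_from_consensus("TGTTTACTTAGC", id = "FKHD12", conc = conc),
       HOX9   = pwm_from_consensus("TTTTATGGC",    id = "HOX9",   conc = conc),
       EBOX8  = pwm_from_consensus("CACCTGTT",     id = "EBOX8",  conc = conc))
}

random_background <- function(n, len, gc) {
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  vapply(seq_len(n), function(i)
    paste(sample(names(probs), len, replace = TRUE, prob = probs),
          collapse = ""),
    character(1))
}

contains_motif <- function(seq, motif_set) {
  any(vapply(motif_set, function(m) {
    cons <- pwm_consensus(m)
    grepl(cons, seq, fixed = TRUE) || grepl(revcomp(cons), seq, fixed = TRUE)
  }, logical(1)))
}

#' Generate a planted-motif enhancer training set
#'
#' Positives are i.i.d. background sequences carrying 1 or more planted motif
#' instances at recorded positions (and strands); negatives are motif-free
#' background with the same GC. Every planted instance is returned in the
#' ground truth, so exact-string scanning of the positives recovers it.
#'
#' @param cfg a [synth_config()].
#' @return list with `sequences` (data.frame: id, seq, label) and `truth`
#'   (data.frame: seq_id, motif_id, start, end, strand, instance).
#' @export
generate_enhancer_set <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(substream_seed(cfg$seed, "enhancers"))
  L <- cfg$seq_len
  widths <- vapply(cfg$motif_set, function(m) ncol(m$mat), 1L)
  if (any(widths > L)) stop("motif longer than seq_len")

  neg <- character(cfg$n_neg)
  for (i in seq_len(cfg$n_neg)) {
    s <- random_background(1L, L, cfg$gc)
    tries <- 0L
    while (contains_motif(s, cfg$motif_set) && tries < 20L) {
      s <- random_background(1L, L, cfg$gc); tries <- tries + 1L
    }
    neg[i] <- s
  }

  pos <- character(cfg$n_pos)
  truth <- vector("list", cfg$n_pos)
  for (i in seq_len(cfg$n_pos)) {
    s <- random_background(1L, L, cfg$gc)
    while (contains_motif(s, cfg$motif_set))
      s <- random_background(1L, L, cfg$gc)
    k <- if (length(cfg$n_instances) == 1L) cfg$n_instances else
      sample(cfg$n_instances, 1L)
    rows <- list()
    occupied <- integer(0)
    for (j in seq_len(k)) {
      mid <- sample(names(cfg$motif_set), 1L)
      m <- cfg$motif_set[[mid]]
      w <- ncol(m$mat)
      # rejection-sample a start that does not overlap earlier plants
      repeat {
        st <- sample.int(L - w + 1L, 1L)
        if (!any((st:(st + w - 1L)) %in% occupied)) break
      }
      occupied <- c(occupied, st:(st + w - 1L))
      inst <- if (cfg$plant == "consensus") pwm_consensus(m) else pwm_sample(m)
      strand <- sample(c("+", "-"), 1L)
      planted <- if (strand == "+") inst else revcomp(inst)
      substr(s, st, st + w - 1L) <- planted
      rows[[j]] <- data.frame(seq_id = sprintf("pos_%d", i), motif_id = mid,
                              start = st, end = st + w - 1L, strand = strand,
                              instance = inst, stringsAsFactors = FALSE)
    }
    pos[i] <- s
    truth[[i]] <- do.call(rbind, rows)
  }

  seqs <- data.frame(
    id = c(sprintf("pos_%d", seq_len(cfg$n_pos)),
           sprintf("neg_%d", seq_len(cfg$n_neg))),
    seq = c(pos, neg),
    label = rep(c(1L, 0L), c(cfg$n_pos, cfg$n_neg)),
    stringsAsFactors = FALSE)
  if (cfg$include_rc && cfg$n_pos > 0L) {
    rc <- data.frame(id = sprintf("pos_%d_rc", seq_len(cfg$n_pos)),
                     seq = revcomp(pos), label = 1L, stringsAsFactors = FALSE)
    seqs <- rbind(seqs, rc)
  }
  truth <- if (cfg$n_pos > 0L) do.call(rbind, truth) else
    data.frame(seq_id = character(0), motif_id = character(0),
               start = integer(0), end = integer(0), strand = character(0),
               instance = character(0))
  list(sequences = seqs, truth = truth)
}

#' Generate a two-population SNP panel on an FST continuum
#'
#' Per SNP an ancestral frequency is drawn uniformly from `anc_range` and
#' population frequencies follow the Balding-Nichols beta model
#' `Beta(p(1-c)/c, (1-p)(1-c)/c)` with drift `c_aa` / `c_ea`. Alleles follow
#' the EA-major reference convention: the EA major allele is the reference,
#' so the recorded alternate-allele frequency in EA is always <= 0.5.
#'
#' @param cfg a [synth_config()].
#' @return data.frame: snp_id, chrom, pos, ref, alt, af_aa, af_ea, p_anc, fst.
#' @export
generate_snp_panel <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(substream_seed(cfg$seed, "panel"))
  fp <- cfg$fst_params
  n <- fp$n_snps
  p <- runif(n, fp$anc_range[1], fp$anc_range[2])
  draw <- function(p, c) {
    if (c < 1e-12) return(p)
    rbeta(length(p), p * (1 - c) / c, (1 - p) * (1 - c) / c)
  }
  af_aa <- draw(p, fp$c_aa)
  af_ea <- draw(p, fp$c_ea)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
  # EA-major convention: flip so the EA major allele is the reference
  flip <- af_ea > 0.5
  af_aa[flip] <- 1 - af_aa[flip]
  af_ea[flip] <- 1 - af_ea[flip]
  tmp <- ref[flip]; ref[flip] <- alt[flip]; alt[flip] <- tmp
  data.frame(snp_id = sprintf("snp_%d", seq_len(n)), chrom = "chrS",
             pos = 5000L + seq_len(n) * 2000L, ref = ref, alt = alt,
             af_aa = af_aa, af_ea = af_ea, p_anc = p,
             fst = fst_hudson(af_aa, af_ea), stringsAsFactors = FALSE)
}

#' Generate heterozygous-site allelic read counts
#'
#' Total depth per site is drawn from the configured distribution; the
#' alternate-read count is binomial with success probability
#' `plogis(effect)`, where the effect is `+effect` log-odds at gained eSNPs,
#' `-effect` at lost eSNPs, and 0 at sites with direction `none` (controls).
#'
#' @param cfg a [synth_config()].
#' @param esnp_calls data.frame with columns `snp_id` and `direction`
#'   (`gained` / `lost` / `none`), e.g. the output of [scan_panel()].
#' @return data.frame: snp_id, direction, true_effect, ref_reads, alt_reads.
#' @export
generate_het_readcounts <- function(cfg, esnp_calls) {
  stopifnot(inherits(cfg, "synth_config"))
  if (NROW(esnp_calls) == 0L)
    return(data.frame(snp_id = character(0), direction = character(0),
                      true_effect = numeric(0), ref_reads = integer(0),
                      alt_reads = integer(0)))
  set.seed(substream_seed(cfg$seed, "readcounts"))
  rp <- cfg$readcount_params
  n <- nrow(esnp_calls)
  depth <- switch(rp$depth_dist,
                  fixed = rep(as.integer(round(rp$depth)), n),
                  nbinom = rnbinom(n, size = rp$depth_size, mu = rp$depth),
                  stop("unknown depth_dist: ", rp$depth_dist))
  eff <- ifelse(esnp_calls$direction == "gained", rp$effect,
                ifelse(esnp_calls$direction == "lost", -rp$effect, 0))
  alt <- rbinom(n, depth, plogis(eff))
  data.frame(snp_id = esnp_calls$snp_id, direction = esnp_calls$direction,
             true_effect = eff, ref_reads = depth - alt, alt_reads = alt,
             stringsAsFactors = FALSE)
}

#' Generate case/control genotypes under a logistic liability model
#'
#' Dosages are drawn per SNP under Hardy-Weinberg at the configured
#' population's allele frequency. A random subset of `n_causal` SNPs gets
#' true risk weights `N(0, weight_scale^2)`; case/control labels are
#' Bernoulli with `plogis(intercept + dosage %*% weights)`, the intercept
#' chosen by bisection so the expected case fraction matches the target.
#'
#' @param cfg a [synth_config()].
#' @param panel SNP panel from [generate_snp_panel()].
#' @return list with `dosages` (individuals x SNPs integer matrix, columns
#'   named by snp_id), `labels` (0/1), and `truth` (list: weights -- full
#'   vector, zero at non-causal SNPs --, intercept, causal snp_ids).
#' @export
generate_genotypes <- function(cfg, panel) {
  stopifnot(inherits(cfg, "synth_config"))
  gp <- cfg$genotype_params
  if (gp$n_causal > nrow(panel))
    stop("n_causal (", gp$n_causal, ") exceeds panel size (", nrow(panel), ")")
  set.seed(substream_seed(cfg$seed, "genotypes"))
  af <- switch(toupper(gp$population), EA = panel$af_ea, AA = panel$af_aa,
               stop("population must be 'EA' or 'AA'"))
  n <- gp$n_individuals
  m <- nrow(panel)
  X <- matrix(rbinom(n * m, 2L, rep(af, each = n)), nrow = n, ncol = m,
              dimnames = list(sprintf("ind_%d", seq_len(n)), panel$snp_id))
  w <- numeric(m)
  causal <- sort(sample.int(m, gp$n_causal))
  w[causal] <- rnorm(gp$n_causal, 0, gp$weight_scale)
  eta <- as.numeric(X %*% w)
  f <- function(b0) mean(plogis(b0 + eta)) - gp$case_fraction
  b0 <- uniroot(f, c(-50, 50))$root
  labels <- rbinom(n, 1L, plogis(b0 + eta))
  list(dosages = X, labels = labels,
       truth = list(weights = setNames(w, panel$snp_id), intercept = b0,
                    causal = panel$snp_id[causal]))
}
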