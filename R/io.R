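#' Read and write the pipeline's tabular and sequence formats
#'
#' Thin wrappers around Biostrings/rtracklayer and base TSV IO with the
#' column contracts used throughout the package: SNP panels
#' (snp_id, chrom, pos 1-based, ref, alt, af_aa, af_ea, ...), allelic read
#' counts (snp_id, ref_reads, alt_reads, direction), and dosage matrices
#' (individuals x SNPs with a `label` column).
#'
#' @param path file path.
#' @name io
NULL

#' @rdname io
#' @param sequences data.frame with id, seq (e.g.
#'   `generate_enhancer_set()$sequences`).
#' @export
write_fasta <- function(sequences, path) {
  dss <- Biostrings::DNAStringSet(sequences$seq)
  names(dss) <- sequences$id
  Biostrings::writeXStringSet(dss, path)
  invisible(path)
}

#' @rdname io
#' @export
read_fasta <- function(path) {
  dss <- Biostrings::readDNAStringSet(path)
  data.frame(id = names(dss), seq = as.character(dss),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @rdname io
#' @export
read_genome <- function(path) {
  as_genome(Biostrings::readDNAStringSet(path))
}

#' @rdname io
#' @param bed a BED file path; returns a `GRanges` (0-based half-open on
#'   disk, 1-based in memory).
#' @export
read_bed <- function(bed) {
  rtracklayer::import(bed, format = "BED")
}

#' @rdname io
#' @param truth planted-motif ground truth
#'   (`generate_enhancer_set()$truth`); written as BED (0-based half-open).
#' @export
write_truth_bed <- function(truth, path) {
  df <- data.frame(chrom = truth$seq_id, start = truth$start - 1L,
                   end = truth$end, name = truth$motif_id, score = 0L,
                   strand = truth$strand)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @param x a data.frame (panel, read counts, EWN calls, ...).
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname io
#' @param genotypes list with `dosages` and `labels`
#'   (`generate_genotypes()` output); written as a TSV with individual id,
#'   label, then one column per SNP.
#' @export
write_dosage_tsv <- function(genotypes, path) {
  df <- data.frame(individual = rownames(genotypes$dosages),
                   label = genotypes$labels,
                   genotypes$dosages, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_dosage_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  dos <- as.matrix(df[, setdiff(names(df), c("individual", "label")),
                      drop = FALSE])
  rownames(dos) <- df$individual
  list(dosages = dos, labels = df$label)
}

#' @rdname io
#' @param af_aa_field,af_ea_field INFO keys holding the per-population
#'   alternate-allele frequencies in a panel VCF.
#' @details `read_panel_vcf()` reads a biallelic-SNV panel from a VCF whose
#'   INFO column carries per-population alternate-allele frequencies;
#'   multi-allelic records and indels are dropped with a message.
#' @export
read_panel_vcf <- function(path, af_aa_field = "AF_AA",
                           af_ea_field = "AF_EA") {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  keep <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    !grepl(",", fix$ALT, fixed = TRUE)
  if (any(!keep))
    message("dropping ", sum(!keep), " non-SNV/multi-allelic record(s)")
  num <- function(field) suppressWarnings(
    as.numeric(vcfR::extract.info(v, element = field)))[keep]
  id <- fix$ID[keep]
  no_id <- is.na(id) | id == "."
  id[no_id] <- paste0(fix$CHROM[keep][no_id], ":", fix$POS[keep][no_id])
  data.frame(snp_id = id, chrom = fix$CHROM[keep],
             pos = as.integer(fix$POS[keep]), ref = fix$REF[keep],
             alt = fix$ALT[keep], af_aa = num(af_aa_field),
             af_ea = num(af_ea_field), stringsAsFactors = FALSE)
}

#' @rdname io
#' @details `read_dosage_vcf()` converts VCF genotypes (GT field) to an
#'   individuals x SNPs alternate-allele dosage matrix; missing genotypes
#'   become `NA` (imputed downstream by [prs_score()]).
#' @export
read_dosage_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  id <- fix$ID
  no_id <- is.na(id) | id == "."
  id[no_id] <- paste0(fix$CHROM[no_id], ":", fix$POS[no_id])
  dosage <- function(g) {
    alleles <- strsplit(gsub("\\|", "/", g), "/", fixed = FALSE)
    vapply(alleles, function(a) {
      if (length(a) == 0L || anyNA(a) || any(a == ".")) return(NA_real_)
      sum(a != "0")
    }, numeric(1))
  }
  d <- t(apply(gt, 1L, dosage))
  out <- t(d)
  dimnames(out) <- list(colnames(gt), id)
  out
}

#' @rdname io
#' @param bam path to an indexed BAM file of allele-informative reads.
#' @param sites data.frame of heterozygous sites: snp_id, chrom, pos, ref,
#'   alt (single bases).
#' @param min_mapq,min_baseq pileup quality filters.
#' @details `read_allelic_counts()` is a convenience pileup reader: it
#'   counts reads supporting the reference and alternate base at each
#'   heterozygous site, ready for [call_imbalance()] once a `direction`
#'   column is attached.
#' @export
read_allelic_counts <- function(bam, sites, min_mapq = 20L, min_baseq = 13L) {
  gr <- GenomicRanges::GRanges(sites$chrom,
                               IRanges::IRanges(sites$pos, sites$pos))
  pp <- Rsamtools::PileupParam(distinguish_strands = FALSE,
                               distinguish_nucleotides = TRUE,
                               min_mapq = min_mapq, min_base_quality = min_baseq,
                               max_depth = 1e6L)
  sbp <- Rsamtools::ScanBamParam(which = gr)
  p <- Rsamtools::pileup(bam, scanBamParam = sbp, pileupParam = pp)
  key <- paste(p$seqnames, p$pos)
  skey <- paste(sites$chrom, sites$pos)
  cnt <- function(base) {
    m <- p$count[match(paste(skey, base), paste(key, p$nucleotide))]
    ifelse(is.na(m), 0L, m)
  }
  data.frame(snp_id = sites$snp_id,
             ref_reads = cnt(toupper(sites$ref)),
             alt_reads = cnt(toupper(sites$alt)),
             stringsAsFactors = FALSE)
}
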