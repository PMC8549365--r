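# Two-SNP haplotype counting for short gene amplicons.

#' Count two-locus gene haplotypes from aligned reads
#'
#' Reads (already aligned to a common coordinate system, i.e. equal length)
#' are quality-masked: bases with Phred quality below \code{min_qual} become
#' N. Each read is then truncated to the two SNP columns; reads carrying an
#' N (or gap) at either column are dropped and the remaining two-base
#' haplotypes are counted.
#'
#' @param reads a \code{Biostrings::QualityScaledDNAStringSet}, or a path to
#'   a FASTQ file of aligned reads.
#' @param snp_positions integer vector of two 1-based alignment columns.
#' @param min_qual minimum Phred quality retained (default 28; lower-quality
#'   bases are conservatively masked to N).
#' @return named integer vector of counts over the observed two-locus
#'   haplotypes (e.g. \code{c(AG = 10, CT = 5)}), with attribute
#'   \code{n_dropped} = number of reads discarded for masked bases.
#' @export
count_gene_haplotypes <- function(reads, snp_positions, min_qual = 28) {
  if (is.character(reads))
    reads <- Biostrings::readQualityScaledDNAStringSet(reads)
  stopifnot(length(snp_positions) == 2L)
  snp_positions <- as.integer(snp_positions)
  widths <- Biostrings::width(reads)
  if (any(snp_positions < 1L) || any(snp_positions > min(widths)))
    ct_error("position_out_of_range", sprintf(
      "SNP columns (%s) outside alignment width %d",
      paste(snp_positions, collapse = ","), min(widths)))
  seqs <- as.character(reads)
  quals <- as(Biostrings::quality(reads), "IntegerList")
  bases <- matrix("", length(seqs), 2L)
  for (k in 1:2) {
    pos <- snp_positions[k]
    b <- substr(seqs, pos, pos)
    q <- vapply(quals, `[`, integer(1), pos)
    b[q < min_qual] <- "N"
    bases[, k] <- b
  }
  hap <- paste0(bases[, 1L], bases[, 2L])
  ok <- !grepl("[^ACGT]", hap)
  counts <- table(hap[ok])
  out <- stats::setNames(as.integer(counts), names(counts))
  out <- out[order(-out, names(out))]
  attr(out, "n_dropped") <- sum(!ok)
  out
}
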