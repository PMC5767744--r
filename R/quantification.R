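# Transcript abundance: RPKM normalization and the expression floor applied
# before gene-expression-marker (GEM) regression.

#' Reads per kilobase of transcript per million aligned reads
#'
#' `rpkm = count / ((cds_length / 1000) * (total_mapped / 1e6))`. Linear in
#' the read count, inverse-linear in CDS length and library size. A zero
#' count gives 0.
#'
#' @param count Mapped read count(s) for the model (vectorized).
#' @param cds_length CDS model length in bases (> 0).
#' @param total_mapped Total aligned reads in the accession's library (> 0).
#' @return RPKM value(s).
#' @examples
#' rpkm(10, 1000, 1e6)      # 10
#' rpkm(52, 2600, 13e6)     # 52 / (2.6 * 13)
#' @export
rpkm <- function(count, cds_length, total_mapped) {
  if (any(cds_length <= 0)) stop("cds_length must be > 0")
  if (any(total_mapped <= 0)) stop("total_mapped must be > 0")
  if (any(count < 0)) stop("count must be >= 0")
  count / ((cds_length / 1000) * (total_mapped / 1e6))
}

#' RPKM matrix from a count table
#'
#' @param counts Numeric matrix of mapped read counts (models x accessions).
#' @param cds_length Named vector of CDS lengths covering `rownames(counts)`.
#' @param total_mapped Named vector of per-accession total aligned reads
#'   covering `colnames(counts)`.
#' @return RPKM matrix with the same dimnames.
#' @export
rpkm_matrix <- function(counts, cds_length, total_mapped) {
  len <- cds_length[rownames(counts)]
  tot <- total_mapped[colnames(counts)]
  if (any(is.na(len))) stop("missing cds_length for some models")
  if (any(is.na(tot))) stop("missing total_mapped for some accessions")
  sweep(sweep(counts, 1, len / 1000, "/"), 2, tot / 1e6, "/")
}

#' Expression floor for GEM analysis
#'
#' Retains CDS models whose mean RPKM across the whole panel (zeros included)
#' is strictly above `min_mean`. Idempotent.
#'
#' @param rpkm Numeric RPKM matrix (models x accessions).
#' @param min_mean Panel-mean RPKM floor, exclusive (default 0.4).
#' @return Character vector of retained model ids.
#' @export
expression_filter <- function(rpkm, min_mean = 0.4) {
  if (!nrow(rpkm)) stop("empty expression matrix")
  rownames(rpkm)[rowMeans(rpkm) > min_mean]
}
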