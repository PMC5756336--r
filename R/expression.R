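# FPKM and the top-quantile "highly transcribed" rule. The quantile is taken
# over the union of all genes in the sample (one cumulative distribution per
# metatranscriptome, not per bin), with the lower nearest-rank convention so
# "top 25%" is an exact count on integer ranks.

#' Compute FPKM from fragment counts
#'
#' FPKM (fragments per kilobase of transcript per million mapped fragments):
#' \deqn{FPKM = f / ((L/1000) (N/10^6))}
#' with \eqn{f} the fragment count, \eqn{L} the gene length in bp and
#' \eqn{N} the library's total mapped fragments. Zero counts give zero.
#'
#' @param fragments data.frame with columns bin_id, gene_id, fragments
#'   (non-negative).
#' @param genes Gene-record data.frame ([gene_records()]) providing lengths;
#'   every counted (bin_id, gene_id) must be present.
#' @param total_mapped_fragments Library total (> 0).
#' @param sample_id Sample label carried into the result.
#' @return An [expression_table()].
#' @export
fpkm <- function(fragments, genes, total_mapped_fragments, sample_id = "sample") {
  stopifnot(is.data.frame(fragments),
            all(c("bin_id", "gene_id", "fragments") %in% names(fragments)))
  if (any(fragments$fragments < 0))
    stop("fragment counts must be >= 0", call. = FALSE)
  if (total_mapped_fragments <= 0)
    stop("total_mapped_fragments must be > 0", call. = FALSE)
  key <- paste(fragments$bin_id, fragments$gene_id, sep = "\r")
  gkey <- paste(genes$bin_id, genes$gene_id, sep = "\r")
  hit <- match(key, gkey)
  if (anyNA(hit)) {
    i <- which(is.na(hit))[1L]
    stop("no gene record for gene '", fragments$gene_id[i], "' in bin '",
         fragments$bin_id[i], "'", call. = FALSE)
  }
  len_kb <- genes$length_bp[hit] / 1000
  million <- total_mapped_fragments / 1e6
  vals <- data.frame(bin_id = fragments$bin_id,
                     gene_id = fragments$gene_id,
                     fpkm = fragments$fragments / (len_kb * million),
                     stringsAsFactors = FALSE)
  expression_table(sample_id, vals, total_mapped_fragments)
}

#' Sample-wide FPKM quantile threshold
#'
#' Empirical quantile of all FPKM values in the sample (all genes across all
#' bins), lower nearest-rank convention (\code{quantile} type 1): for
#' \eqn{n} values the threshold is the \eqn{\lceil qn \rceil}-th order
#' statistic. With the default \code{quantile = 0.75}, genes strictly above
#' the threshold are the "top 25%".
#'
#' @param table An [expression_table()].
#' @param quantile Fraction in (0, 1); default 0.75.
#' @return The threshold FPKM value.
#' @export
expression_threshold <- function(table, quantile = 0.75) {
  stopifnot(inherits(table, "expression_table"))
  x <- table$values$fpkm
  if (length(x) == 0L) stop("expression table is empty", call. = FALSE)
  unname(stats::quantile(x, probs = quantile, type = 1, names = FALSE))
}

#' Classify highly transcribed genes
#'
#' Flags genes whose FPKM strictly exceeds the threshold; ties at the
#' threshold are not flagged.
#'
#' @param table An [expression_table()].
#' @param threshold Non-negative FPKM cutoff, typically from
#'   [expression_threshold()].
#' @return data.frame with columns bin_id, gene_id, fpkm,
#'   highly_transcribed.
#' @export
classify_highly_transcribed <- function(table, threshold) {
  stopifnot(inherits(table, "expression_table"), threshold >= 0)
  out <- table$values
  out$highly_transcribed <- out$fpkm > threshold
  out
}
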