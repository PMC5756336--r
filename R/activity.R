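# Active-member profiling: genome-size-normalized abundance from the DNA
# library, then the cDNA/DNA mapping-rate ratio as the in-situ transcription
# proxy. Both rates use total library reads as denominator against the same
# bin target set; the target scope is recorded as an attribute so asymmetric
# upstream mapping (e.g. cDNA vs CDS only) stays documented, not silently
# assumed.

#' Genome-size-normalized relative abundance
#'
#' Raw mapped-read counts over-represent large genomes, so counts are divided
#' by genome size before normalizing:
#' \deqn{a_i = (m_i / L_i) / \sum_j (m_j / L_j)}
#' where \eqn{m_i} is the mapped-read count and \eqn{L_i} the genome size of
#' bin \eqn{i}. The result sums to 1 over the mapped bins and is invariant
#' under uniform scaling of sequencing depth.
#'
#' @param dna A DNA-library [read_mapping_summary()].
#' @param bins List of [genome_bin()] objects covering every mapped bin.
#' @return Named numeric vector of abundance fractions, sorted by bin_id.
#' @export
relative_abundance <- function(dna, bins) {
  stopifnot(inherits(dna, "read_mapping_summary"))
  if (dna$library_type != "DNA")
    stop("relative abundance is defined on the DNA library", call. = FALSE)
  sizes <- vapply(bins, `[[`, 1, "genome_size")
  names(sizes) <- vapply(bins, `[[`, "", "bin_id")
  missing <- setdiff(names(dna$mapped_reads), names(sizes))
  if (length(missing))
    stop("no genome size for mapped bin(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  m <- dna$mapped_reads
  if (all(m == 0)) stop("no mapped reads", call. = FALSE)
  w <- m / sizes[names(m)]
  w / sum(w)
}

#' Per-bin cDNA/DNA mapping-rate ratios
#'
#' Each library's per-bin mapping rate is mapped reads over total library
#' reads; the activity ratio is the cDNA rate divided by the DNA rate, which
#' cancels sequencing depth in both libraries. Bins without DNA signal get an
#' undefined (\code{NA}) ratio rather than infinity and are never active.
#'
#' @param cdna,dna [read_mapping_summary()] objects of library type cDNA and
#'   DNA over the same bin set.
#' @return data.frame of class \code{activity_profiles} with columns bin_id,
#'   dna_rate, cdna_rate, ratio, active (initialized \code{FALSE}; see
#'   [classify_active()]). Attribute \code{target_scope} records that both
#'   rates were computed against the bin set shared by the two summaries.
#' @export
cdna_dna_ratio <- function(cdna, dna) {
  stopifnot(inherits(cdna, "read_mapping_summary"),
            inherits(dna, "read_mapping_summary"))
  if (cdna$library_type != "cDNA" || dna$library_type != "DNA")
    stop("arguments must be the cDNA and DNA summaries, in that order",
         call. = FALSE)
  only_c <- setdiff(names(cdna$mapped_reads), names(dna$mapped_reads))
  only_d <- setdiff(names(dna$mapped_reads), names(cdna$mapped_reads))
  if (length(only_c) || length(only_d))
    stop("bin sets differ between libraries; cDNA-only: {",
         paste(only_c, collapse = ", "), "}, DNA-only: {",
         paste(only_d, collapse = ", "), "}", call. = FALSE)
  ids <- sort(names(dna$mapped_reads))
  dna_rate <- dna$mapped_reads[ids] / dna$total_reads
  cdna_rate <- cdna$mapped_reads[ids] / cdna$total_reads
  ratio <- ifelse(dna_rate > 0, cdna_rate / dna_rate, NA_real_)
  out <- data.frame(bin_id = ids,
                    dna_rate = unname(dna_rate),
                    cdna_rate = unname(cdna_rate),
                    ratio = unname(ratio),
                    active = FALSE,
                    stringsAsFactors = FALSE)
  attr(out, "target_scope") <- "shared bin set; rates over total library reads"
  class(out) <- c("activity_profiles", "data.frame")
  out
}

#' Classify active community members
#'
#' A bin is active when its cDNA/DNA ratio strictly exceeds the threshold
#' (default 0.5). Ties at the threshold and undefined ratios are inactive.
#'
#' @param profiles data.frame from [cdna_dna_ratio()].
#' @param threshold Activity cutoff; strict \code{>} comparison.
#' @return \code{profiles} with the \code{active} column set; the active bin
#'   ids are available as \code{attr(, "active_bins")} and via
#'   [active_bins()].
#' @export
classify_active <- function(profiles, threshold = 0.5) {
  stopifnot(is.data.frame(profiles))
  profiles$active <- !is.na(profiles$ratio) & profiles$ratio > threshold
  attr(profiles, "active_bins") <- profiles$bin_id[profiles$active]
  profiles
}

#' Active bin ids from a classified profile table
#'
#' @param profiles Output of [classify_active()].
#' @return Character vector of active bin ids.
#' @export
active_bins <- function(profiles) {
  profiles$bin_id[profiles$active]
}
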