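#' Construct a genome bin
#'
#' A genome bin (metagenome-assembled genome, MAG) is a draft genome recovered
#' by differential-coverage binning, carrying the quality metrics estimated by
#' tools such as CheckM and an inventory of orthology gene identifiers from
#' annotation. Gene identifiers are opaque strings (KO-style labels); no
#' annotation lookup is performed here.
#'
#' @param bin_id Character scalar, unique within a community.
#' @param taxonomy Free-text taxonomic label.
#' @param genome_size Genome size in base pairs (> 0).
#' @param completeness,contamination Fractions in \code{[0, 1]}. File readers
#'   accept CheckM-style percentages and convert; constructors take fractions.
#' @param genes Character vector of orthology gene identifiers present in the
#'   bin. Stored sorted and unique.
#' @param transporters Character vector of compound identifiers for which the
#'   bin carries a dedicated transporter. Stored sorted and unique.
#' @return An object of class \code{genome_bin}.
#' @export
genome_bin <- function(bin_id, taxonomy = "", genome_size,
                       completeness = 1, contamination = 0,
                       genes = character(), transporters = character()) {
  if (!is.character(bin_id) || length(bin_id) != 1L || !nzchar(bin_id))
    stop("bin_id must be a non-empty character scalar", call. = FALSE)
  genome_size <- as.numeric(genome_size)
  if (!is.finite(genome_size) || genome_size <= 0)
    stop("genome_size must be > 0 for bin '", bin_id, "'", call. = FALSE)
  completeness <- as.numeric(completeness)
  contamination <- as.numeric(contamination)
  if (!is.finite(completeness) || completeness < 0 || completeness > 1)
    stop("completeness must lie in [0, 1] for bin '", bin_id,
         "' (got ", completeness, "); percentages belong in file input only",
         call. = FALSE)
  if (!is.finite(contamination) || contamination < 0 || contamination > 1)
    stop("contamination must lie in [0, 1] for bin '", bin_id, "'",
         call. = FALSE)
  structure(
    list(
      bin_id = bin_id,
      taxonomy = as.character(taxonomy),
      genome_size = genome_size,
      completeness = completeness,
      contamination = contamination,
      genes = sort(unique(as.character(genes))),
      transporters = sort(unique(as.character(transporters)))
    ),
    class = "genome_bin"
  )
}

#' @export
print.genome_bin <- function(x, ...) {
  cat(sprintf("<genome_bin> %s (%s)\n  %.2f Mb, completeness %.1f%%, contamination %.1f%%, %d genes, %d transporters\n",
              x$bin_id, x$taxonomy, x$genome_size / 1e6,
              100 * x$completeness, 100 * x$contamination,
              length(x$genes), length(x$transporters)))
  invisible(x)
}

#' Construct a biosynthetic pathway definition
#'
#' A pathway is an ordered list of reaction steps; each step is an OR-group of
#' alternative gene identifiers (isoenzymes), any one of which satisfies the
#' step. \code{transporter_relevant} is \code{FALSE} for compounds that do not
#' need a dedicated uptake system (vitamins B2 and B3), so transporter
#' presence is reported as not-applicable for them.
#'
#' @param compound_id Compound name (amino acid or vitamin), unique per set.
#' @param compound_class \code{"amino_acid"} or \code{"vitamin"}.
#' @param steps List of non-empty character vectors, one OR-group per step.
#' @param transporter_relevant Logical scalar.
#' @param cost_rank Integer display rank by biosynthetic cost (1 = cheapest).
#' @return An object of class \code{pathway_definition}.
#' @export
pathway_definition <- function(compound_id,
                               compound_class = c("amino_acid", "vitamin"),
                               steps, transporter_relevant = TRUE,
                               cost_rank = NA_integer_) {
  compound_class <- match.arg(compound_class)
  if (!is.character(compound_id) || length(compound_id) != 1L || !nzchar(compound_id))
    stop("compound_id must be a non-empty character scalar", call. = FALSE)
  if (!is.list(steps) || length(steps) == 0L)
    stop("pathway '", compound_id, "' must have at least one step", call. = FALSE)
  steps <- lapply(steps, function(s) sort(unique(as.character(s))))
  if (any(vapply(steps, length, 1L) == 0L))
    stop("pathway '", compound_id, "' contains an empty OR-group", call. = FALSE)
  structure(
    list(
      compound_id = compound_id,
      compound_class = compound_class,
      transporter_relevant = isTRUE(transporter_relevant),
      cost_rank = as.integer(cost_rank),
      steps = steps
    ),
    class = "pathway_definition"
  )
}

#' Gene length records
#'
#' Per-bin gene records carry the length (bp) used in the FPKM denominator.
#' The same orthology identifier may occur in several bins with different
#' lengths; records are keyed by (bin_id, gene_id).
#'
#' @param gene_id,bin_id Character vectors.
#' @param length_bp Positive integer lengths in base pairs.
#' @return A data.frame with columns gene_id, bin_id, length_bp.
#' @export
gene_records <- function(gene_id, bin_id, length_bp) {
  length_bp <- as.numeric(length_bp)
  if (any(!is.finite(length_bp) | length_bp <= 0))
    stop("gene lengths must be > 0 bp", call. = FALSE)
  df <- data.frame(gene_id = as.character(gene_id),
                   bin_id = as.character(bin_id),
                   length_bp = length_bp,
                   stringsAsFactors = FALSE)
  key <- paste(df$bin_id, df$gene_id, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (bin_id, gene_id) in gene records: ",
         paste(unique(df$gene_id[duplicated(key)]), collapse = ", "),
         call. = FALSE)
  df <- df[order(df$bin_id, df$gene_id), c("gene_id", "bin_id", "length_bp")]
  rownames(df) <- NULL
  df
}

#' Construct a read-mapping summary for one sequencing library
#'
#' Summarizes how many reads of a DNA (metagenome) or cDNA (metatranscriptome)
#' library mapped to each genome bin. Bins are non-overlapping mapping
#' targets, so mapped counts may not exceed the library total; the remainder
#' is unmapped (e.g. unbinned contigs, inactive injection-water organisms).
#'
#' @param sample_id Sample identifier.
#' @param library_type \code{"DNA"} or \code{"cDNA"}.
#' @param total_reads Total reads in the library (> 0).
#' @param mapped_reads Named numeric vector, bin_id -> mapped read count.
#' @return An object of class \code{read_mapping_summary}.
#' @export
read_mapping_summary <- function(sample_id, library_type = c("DNA", "cDNA"),
                                 total_reads, mapped_reads) {
  library_type <- match.arg(library_type)
  total_reads <- as.numeric(total_reads)
  mapped_reads <- unlist(mapped_reads)
  if (is.null(names(mapped_reads)) || any(!nzchar(names(mapped_reads))))
    stop("mapped_reads must be named by bin_id", call. = FALSE)
  if (anyDuplicated(names(mapped_reads)))
    stop("duplicate bin_id in mapped_reads", call. = FALSE)
  if (any(mapped_reads < 0))
    stop("mapped read counts must be >= 0", call. = FALSE)
  if (!is.finite(total_reads) || total_reads <= 0)
    stop("total_reads must be > 0", call. = FALSE)
  if (sum(mapped_reads) > total_reads)
    stop("sum of mapped reads (", sum(mapped_reads),
         ") exceeds total_reads (", total_reads, ") for sample '",
         sample_id, "' [", library_type, "]", call. = FALSE)
  mapped_reads <- mapped_reads[order(names(mapped_reads))]
  structure(
    list(sample_id = as.character(sample_id),
         library_type = library_type,
         total_reads = total_reads,
         mapped_reads = mapped_reads),
    class = "read_mapping_summary"
  )
}

#' Construct an expression table
#'
#' Holds length- and depth-normalized expression (FPKM) per (bin, gene) for
#' one metatranscriptome sample, plus the library size used as the
#' per-million denominator. Usually produced by [fpkm()].
#'
#' @param sample_id Sample identifier.
#' @param values data.frame with columns bin_id, gene_id, fpkm (all >= 0).
#' @param total_mapped_fragments Positive library total.
#' @return An object of class \code{expression_table}.
#' @export
expression_table <- function(sample_id, values, total_mapped_fragments) {
  stopifnot(is.data.frame(values),
            all(c("bin_id", "gene_id", "fpkm") %in% names(values)))
  if (any(!is.finite(values$fpkm) | values$fpkm < 0))
    stop("FPKM values must be finite and >= 0", call. = FALSE)
  total_mapped_fragments <- as.numeric(total_mapped_fragments)
  if (!is.finite(total_mapped_fragments) || total_mapped_fragments <= 0)
    stop("total_mapped_fragments must be > 0", call. = FALSE)
  values <- values[order(values$bin_id, values$gene_id),
                   c("bin_id", "gene_id", "fpkm"), drop = FALSE]
  rownames(values) <- NULL
  structure(
    list(sample_id = as.character(sample_id),
         values = values,
         total_mapped_fragments = total_mapped_fragments),
    class = "expression_table"
  )
}

#' Assemble a community object
#'
#' Bundles bins, gene records and pathway definitions after cross-reference
#' checks: bin ids unique, every gene record resolves to a known bin.
#'
#' @param bins List of [genome_bin()] objects.
#' @param genes Gene-record data.frame (see [gene_records()]); may have 0 rows.
#' @param pathways List of [pathway_definition()] objects.
#' @return An object of class \code{community} with elements \code{bins}
#'   (named list, sorted by bin_id), \code{genes}, \code{pathways} (named
#'   list, sorted by cost_rank then compound_id).
#' @export
community <- function(bins, genes = gene_records(character(), character(), numeric()),
                      pathways = list()) {
  if (length(bins) == 0L) stop("a community needs at least one bin", call. = FALSE)
  stopifnot(all(vapply(bins, inherits, TRUE, "genome_bin")))
  ids <- vapply(bins, `[[`, "", "bin_id")
  if (anyDuplicated(ids))
    stop("duplicate bin_id: ", paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  names(bins) <- ids
  bins <- bins[order(ids)]
  unknown <- setdiff(unique(genes$bin_id), ids)
  if (length(unknown))
    stop("gene records reference unknown bin(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  stopifnot(all(vapply(pathways, inherits, TRUE, "pathway_definition")))
  cids <- vapply(pathways, `[[`, "", "compound_id")
  if (anyDuplicated(cids))
    stop("duplicate compound_id: ",
         paste(unique(cids[duplicated(cids)]), collapse = ", "), call. = FALSE)
  names(pathways) <- cids
  if (length(pathways)) {
    rk <- vapply(pathways, `[[`, 1L, "cost_rank")
    pathways <- pathways[order(rk, cids)]
  }
  structure(list(bins = bins, genes = genes, pathways = pathways),
            class = "community")
}

#' @export
print.community <- function(x, ...) {
  cat(sprintf("<community> %d bins, %d gene records, %d pathways\n",
              length(x$bins), nrow(x$genes), length(x$pathways)))
  invisible(x)
}
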