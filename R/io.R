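# File formats are plain TSV plus one JSON pathway file. The upstream tools
# these tables mimic (binning QC, annotation servers, aligners) emit ad-hoc
# tables with no portable schema, so the schema here is the package's own and
# is documented in ?read_community.

.read_tsv_checked <- function(path, required_cols) {
  if (!file.exists(path))
    stop("missing input file: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = NULL)
  missing <- setdiff(required_cols, names(df))
  if (length(missing))
    stop(basename(path), ": missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  df
}

.num_field <- function(x, file, col) {
  suppressWarnings(v <- as.numeric(x))
  bad <- which(!is.finite(v))
  if (length(bad))
    stop(file, " line ", bad[1L] + 1L, ": column '", col,
         "' is not numeric ('", x[bad[1L]], "')", call. = FALSE)
  v
}

.split_ids <- function(x) {
  if (!nzchar(x)) character() else strsplit(x, ",", fixed = TRUE)[[1L]]
}

#' Read a community directory
#'
#' Reads \code{bins.tsv}, \code{genes.tsv} and \code{pathways.json} from a
#' directory and returns a cross-referenced [community()] object.
#'
#' File schemas:
#' \itemize{
#'   \item \code{bins.tsv}: \code{bin_id}, \code{taxonomy},
#'     \code{genome_size_bp}, \code{completeness_pct},
#'     \code{contamination_pct}, \code{gene_ids} (comma-joined),
#'     \code{transporter_compounds} (comma-joined). Completeness and
#'     contamination are percentages on file (CheckM convention) and
#'     fractions in memory.
#'   \item \code{genes.tsv}: \code{gene_id}, \code{bin_id}, \code{length_bp}.
#'   \item \code{pathways.json}: array of objects with \code{compound_id},
#'     \code{compound_class}, \code{transporter_relevant}, \code{cost_rank},
#'     \code{steps} (array of arrays of gene ids).
#' }
#'
#' @param dir_path Directory containing the three files.
#' @return A [community()] object.
#' @seealso [write_community()], [validate_community()]
#' @export
read_community <- function(dir_path) {
  bins_df <- .read_tsv_checked(file.path(dir_path, "bins.tsv"),
                               c("bin_id", "taxonomy", "genome_size_bp",
                                 "completeness_pct", "contamination_pct",
                                 "gene_ids", "transporter_compounds"))
  genes_df <- .read_tsv_checked(file.path(dir_path, "genes.tsv"),
                                c("gene_id", "bin_id", "length_bp"))
  ppath <- file.path(dir_path, "pathways.json")
  if (!file.exists(ppath))
    stop("missing input file: ", ppath, call. = FALSE)
  praw <- jsonlite::fromJSON(ppath, simplifyVector = FALSE)

  if (anyDuplicated(bins_df$bin_id))
    stop("bins.tsv: duplicate bin_id '",
         bins_df$bin_id[duplicated(bins_df$bin_id)][1L], "'", call. = FALSE)
  sizes <- .num_field(bins_df$genome_size_bp, "bins.tsv", "genome_size_bp")
  comp <- .num_field(bins_df$completeness_pct, "bins.tsv", "completeness_pct")
  cont <- .num_field(bins_df$contamination_pct, "bins.tsv", "contamination_pct")
  bins <- lapply(seq_len(nrow(bins_df)), function(i) {
    genome_bin(bin_id = bins_df$bin_id[i],
               taxonomy = bins_df$taxonomy[i],
               genome_size = sizes[i],
               completeness = comp[i] / 100,
               contamination = cont[i] / 100,
               genes = .split_ids(bins_df$gene_ids[i]),
               transporters = .split_ids(bins_df$transporter_compounds[i]))
  })

  if (nrow(genes_df)) {
    lens <- .num_field(genes_df$length_bp, "genes.tsv", "length_bp")
    unknown <- which(!(genes_df$bin_id %in% bins_df$bin_id))
    if (length(unknown))
      stop("genes.tsv line ", unknown[1L] + 1L,
           ": unknown bin '", genes_df$bin_id[unknown[1L]], "'", call. = FALSE)
    genes <- gene_records(genes_df$gene_id, genes_df$bin_id, lens)
  } else {
    genes <- gene_records(character(), character(), numeric())
  }

  pathways <- lapply(praw, function(p) {
    pathway_definition(compound_id = p$compound_id,
                       compound_class = p$compound_class,
                       steps = lapply(p$steps, function(s) unlist(s)),
                       transporter_relevant = isTRUE(p$transporter_relevant),
                       cost_rank = p$cost_rank)
  })
  community(bins, genes, pathways)
}

#' Write a community directory
#'
#' Inverse of [read_community()]; output is canonical (records sorted by id),
#' so byte-identical files result from any input ordering of the same data.
#'
#' @param comm A [community()] object.
#' @param dir_path Output directory (created if needed).
#' @return \code{dir_path}, invisibly.
#' @export
write_community <- function(comm, dir_path) {
  stopifnot(inherits(comm, "community"))
  dir.create(dir_path, recursive = TRUE, showWarnings = FALSE)
  bins_df <- do.call(rbind, lapply(comm$bins, function(b) {
    data.frame(bin_id = b$bin_id, taxonomy = b$taxonomy,
               genome_size_bp = format(b$genome_size, scientific = FALSE),
               completeness_pct = format(100 * b$completeness, digits = 15),
               contamination_pct = format(100 * b$contamination, digits = 15),
               gene_ids = paste(b$genes, collapse = ","),
               transporter_compounds = paste(b$transporters, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(bins_df, file.path(dir_path, "bins.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  genes <- comm$genes[order(comm$genes$bin_id, comm$genes$gene_id), , drop = FALSE]
  utils::write.table(genes, file.path(dir_path, "genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  plist <- lapply(comm$pathways, function(p) {
    list(compound_id = p$compound_id, compound_class = p$compound_class,
         transporter_relevant = p$transporter_relevant,
         cost_rank = p$cost_rank, steps = p$steps)
  })
  jsonlite::write_json(unname(plist), file.path(dir_path, "pathways.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir_path)
}

#' Read read-mapping summaries
#'
#' \code{mapping.tsv} is long-format with columns \code{sample_id},
#' \code{library_type}, \code{total_reads}, \code{bin_id},
#' \code{mapped_reads}; rows sharing (sample_id, library_type) form one
#' library summary.
#'
#' @param path Path to mapping.tsv.
#' @return Named list of [read_mapping_summary()] objects, names
#'   \code{"<sample_id>:<library_type>"}.
#' @export
read_mapping <- function(path) {
  df <- .read_tsv_checked(path, c("sample_id", "library_type", "total_reads",
                                  "bin_id", "mapped_reads"))
  if (!nrow(df)) return(list())
  df$total_reads <- .num_field(df$total_reads, basename(path), "total_reads")
  df$mapped_reads <- .num_field(df$mapped_reads, basename(path), "mapped_reads")
  key <- paste(df$sample_id, df$library_type, sep = ":")
  out <- lapply(split(df, key), function(g) {
    if (length(unique(g$total_reads)) != 1L)
      stop(basename(path), ": inconsistent total_reads within library ",
           g$sample_id[1L], ":", g$library_type[1L], call. = FALSE)
    read_mapping_summary(g$sample_id[1L], g$library_type[1L],
                         g$total_reads[1L],
                         stats::setNames(g$mapped_reads, g$bin_id))
  })
  out[sort(names(out))]
}

#' Write read-mapping summaries
#'
#' @param summaries List of [read_mapping_summary()] objects.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_mapping <- function(summaries, path) {
  rows <- do.call(rbind, lapply(summaries, function(s) {
    data.frame(sample_id = s$sample_id, library_type = s$library_type,
               total_reads = s$total_reads,
               bin_id = names(s$mapped_reads),
               mapped_reads = unname(s$mapped_reads),
               stringsAsFactors = FALSE)
  }))
  rows <- rows[order(rows$sample_id, rows$library_type, rows$bin_id), , drop = FALSE]
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read fragment counts and library totals
#'
#' \code{expression.tsv} has columns \code{sample_id}, \code{bin_id},
#' \code{gene_id}, \code{fragments}; the companion \code{totals.tsv} has
#' \code{sample_id}, \code{total_mapped_fragments}.
#'
#' @param counts_path,totals_path File paths.
#' @return Named list per sample with elements \code{fragments} (data.frame
#'   bin_id, gene_id, fragments) and \code{total_mapped_fragments}.
#' @export
read_fragment_counts <- function(counts_path, totals_path) {
  cdf <- .read_tsv_checked(counts_path,
                           c("sample_id", "bin_id", "gene_id", "fragments"))
  tdf <- .read_tsv_checked(totals_path,
                           c("sample_id", "total_mapped_fragments"))
  cdf$fragments <- .num_field(cdf$fragments, basename(counts_path), "fragments")
  tdf$total_mapped_fragments <- .num_field(tdf$total_mapped_fragments,
                                           basename(totals_path),
                                           "total_mapped_fragments")
  out <- lapply(split(tdf, tdf$sample_id), function(t1) {
    g <- cdf[cdf$sample_id == t1$sample_id[1L], c("bin_id", "gene_id", "fragments")]
    rownames(g) <- NULL
    list(fragments = g, total_mapped_fragments = t1$total_mapped_fragments[1L])
  })
  out[sort(names(out))]
}

#' Write fragment counts and totals
#'
#' @param samples Named list as returned by [read_fragment_counts()].
#' @param counts_path,totals_path Output paths.
#' @return \code{counts_path}, invisibly.
#' @export
write_fragment_counts <- function(samples, counts_path, totals_path) {
  rows <- do.call(rbind, lapply(names(samples), function(sid) {
    g <- samples[[sid]]$fragments
    data.frame(sample_id = sid, g, stringsAsFactors = FALSE)
  }))
  rows <- rows[order(rows$sample_id, rows$bin_id, rows$gene_id), , drop = FALSE]
  utils::write.table(rows, counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  tdf <- data.frame(sample_id = names(samples),
                    total_mapped_fragments =
                      vapply(samples, `[[`, 1, "total_mapped_fragments"))
  tdf <- tdf[order(tdf$sample_id), , drop = FALSE]
  utils::write.table(tdf, totals_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(counts_path)
}

#' Write the auxotrophy matrix file
#'
#' Tab-separated matrix with one row per compound (ordered by biosynthetic
#' cost rank, then compound id) and one column per bin (sorted by id). Each
#' cell is \code{"<status>;<T|F|NA>"}: the call status and the transporter
#' flag (\code{NA} where a transporter is not required for the compound).
#' Output is byte-identical for identical call sets regardless of input
#' order.
#'
#' @param calls Auxotrophy-call data.frame from [auxotrophy_matrix()]; must
#'   cover a complete bins-by-compounds grid.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_auxotrophy_matrix <- function(calls, path) {
  stopifnot(is.data.frame(calls))
  bins <- sort(unique(calls$bin_id))
  key <- paste(calls$compound_id, calls$bin_id, sep = "\r")
  cmp <- unique(calls[order(calls$cost_rank, calls$compound_id),
                      c("compound_id", "cost_rank")])
  want <- as.vector(outer(cmp$compound_id, bins, paste, sep = "\r"))
  absent <- setdiff(want, key)
  if (length(absent) || anyDuplicated(key))
    stop("calls do not form a complete bins x compounds grid; missing: ",
         paste(gsub("\r", " x ", utils::head(absent, 5L)), collapse = "; "),
         call. = FALSE)
  tr <- ifelse(is.na(calls$transporter_present), "NA",
               ifelse(calls$transporter_present, "T", "F"))
  cell <- stats::setNames(paste(calls$status, tr, sep = ";"), key)
  mat <- matrix(cell[want], nrow = nrow(cmp), ncol = length(bins),
                dimnames = list(cmp$compound_id, bins))
  lines <- c(paste(c("compound", bins), collapse = "\t"),
             vapply(seq_len(nrow(mat)), function(i)
               paste(c(rownames(mat)[i], mat[i, ]), collapse = "\t"), ""))
  writeLines(lines, path)
  invisible(path)
}

#' Read an auxotrophy matrix file
#'
#' @param path Path written by [write_auxotrophy_matrix()].
#' @return data.frame with columns compound_id, bin_id, status,
#'   transporter_present, cost_rank (row order in file).
#' @export
read_auxotrophy_matrix <- function(path) {
  df <- .read_tsv_checked(path, "compound")
  bins <- setdiff(names(df), "compound")
  out <- do.call(rbind, lapply(seq_len(nrow(df)), function(i) {
    parts <- strsplit(unlist(df[i, bins]), ";", fixed = TRUE)
    data.frame(compound_id = df$compound[i], bin_id = bins,
               status = vapply(parts, `[[`, "", 1L),
               transporter_present = vapply(parts, function(p)
                 switch(p[[2L]], T = TRUE, F = FALSE, NA), NA),
               cost_rank = i, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Validate a community directory
#'
#' Reads a community directory and re-checks every structural invariant
#' (ranges, uniqueness, referential integrity). Errors are signalled with the
#' offending file, line or identifier.
#'
#' @param dir_path Community directory.
#' @return The validated [community()] object, invisibly.
#' @export
validate_community <- function(dir_path) {
  invisible(read_community(dir_path))
}
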