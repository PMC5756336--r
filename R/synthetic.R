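# Synthetic communities with planted ground truth. The generator emulates the
# *tabular outputs* of an upstream binning + annotation + read-mapping
# pipeline (no sequence content): bins with quality metrics, per-bin gene
# inventories, pathway definitions, multinomial read-mapping summaries and
# Poisson fragment counts. Each stage draws from its own pseudo-random stream
# keyed by (seed, stage name) so stages can be regenerated independently.

.aa_by_cost <- c("glycine", "alanine", "aspartate", "serine", "glutamate",
                 "asparagine", "glutamine", "threonine", "proline", "valine",
                 "cysteine", "leucine", "arginine", "lysine", "isoleucine",
                 "methionine", "histidine", "tyrosine", "phenylalanine",
                 "tryptophan")
.vitamins <- c("B1", "B2", "B3", "B5", "B6", "B7", "B9", "B12", "K2")
.no_transporter_needed <- c("B2", "B3")

.stage_seed <- function(seed, stage) {
  ints <- utf8ToInt(stage)
  h <- sum(ints * seq_along(ints)) %% 99991L
  as.integer((abs(as.numeric(seed)) * 7919 + h * 104729) %% 2147483647)
}

#' Configuration for the synthetic-community generator
#'
#' Defaults describe a mid-size community of 20 bins and the 20 amino-acid
#' pathways, with 30\% planted auxotrophs, 10\% of prototrophs missing
#' exactly one gene while expressing the pathway (exercising the rescue
#' rule), log-normal expression variation, and sequencing depths of one
#' million reads per library with a 30\% unmapped fraction emulating the
#' inactive injection-water flora.
#'
#' @param n_bins Number of genome bins (>= 2 when
#'   \code{single_missing_prototroph_rate > 0}, since rescue needs a
#'   complete-pathway reference bin).
#' @param n_compounds Number of compounds (first the 20 amino acids in
#'   biosynthetic-cost order, then 9 vitamins; max 29).
#' @param steps_per_pathway,or_group_size Integer ranges \code{c(min, max)}.
#' @param auxotroph_rate Probability a bin x compound pair is a planted
#'   auxotroph.
#' @param single_missing_prototroph_rate Fraction of prototroph pairs planted
#'   with exactly one absent gene but full pathway expression.
#' @param low_expression_auxotroph_rate Fraction of auxotroph pairs planted
#'   as a single missing step with the remaining pathway genes expressed at
#'   \code{low_expression_factor} times the normal level (the "low overall
#'   transcription" auxotrophy route).
#' @param low_expression_factor Expression multiplier for those pathways.
#' @param expression_noise_sd Log-scale SD of per-gene expression means.
#' @param dna_depth,cdna_depth Library sizes (reads / fragments).
#' @param unmapped_fraction Fraction of reads mapping to no bin.
#' @param count_noise If \code{FALSE}, Poisson fragment counts are replaced
#'   by their expectations (noiseless limit).
#' @param seed Integer master seed.
#' @return Object of class \code{generator_config}.
#' @export
generator_config <- function(n_bins = 20L, n_compounds = 20L,
                             steps_per_pathway = c(3L, 6L),
                             or_group_size = c(1L, 2L),
                             auxotroph_rate = 0.3,
                             single_missing_prototroph_rate = 0.1,
                             low_expression_auxotroph_rate = 0.25,
                             low_expression_factor = 0.1,
                             expression_noise_sd = 0.5,
                             dna_depth = 1e6, cdna_depth = 1e6,
                             unmapped_fraction = 0.3,
                             count_noise = TRUE,
                             seed = 1L) {
  rates <- c(auxotroph_rate, single_missing_prototroph_rate,
             low_expression_auxotroph_rate, unmapped_fraction)
  if (any(rates < 0 | rates > 1))
    stop("rates must lie in [0, 1]", call. = FALSE)
  if (dna_depth <= 0 || cdna_depth <= 0)
    stop("sequencing depths must be > 0", call. = FALSE)
  if (expression_noise_sd < 0)
    stop("expression_noise_sd must be >= 0", call. = FALSE)
  if (n_compounds < 1L || n_compounds > length(.aa_by_cost) + length(.vitamins))
    stop("n_compounds must be between 1 and ",
         length(.aa_by_cost) + length(.vitamins), call. = FALSE)
  if (n_bins < 2L && single_missing_prototroph_rate > 0)
    stop("n_bins must be >= 2 when single_missing_prototroph_rate > 0: ",
         "the rescue rule needs a complete-pathway reference bin",
         call. = FALSE)
  structure(list(n_bins = as.integer(n_bins),
                 n_compounds = as.integer(n_compounds),
                 steps_per_pathway = as.integer(steps_per_pathway),
                 or_group_size = as.integer(or_group_size),
                 auxotroph_rate = auxotroph_rate,
                 single_missing_prototroph_rate = single_missing_prototroph_rate,
                 low_expression_auxotroph_rate = low_expression_auxotroph_rate,
                 low_expression_factor = low_expression_factor,
                 expression_noise_sd = expression_noise_sd,
                 dna_depth = dna_depth, cdna_depth = cdna_depth,
                 unmapped_fraction = unmapped_fraction,
                 count_noise = isTRUE(count_noise),
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Generate a synthetic community with planted ground truth
#'
#' Plants, per bin x compound: prototroph with a complete pathway,
#' single-gap prototroph (one step absent, pathway expressed normally),
#' multi-gap auxotroph (>= 2 steps absent), or low-expression auxotroph (one
#' step absent, remaining genes weakly expressed). Genome sizes are drawn in
#' 1--6 Mb, abundances from a normalized Gamma (Dirichlet) draw, activity
#' multipliers log-normally. Per-(bin, gene) expected FPKM is the pathway or
#' housekeeping baseline times log-normal noise of SD
#' \code{expression_noise_sd}. Fully deterministic given the config seed.
#'
#' @param config A [generator_config()].
#' @return List with elements \code{community} (a [community()]),
#'   \code{truth} (status_truth, abundance_truth, activity_truth,
#'   expressed_mean) and \code{config}.
#' @export
generate_community <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(.stage_seed(config$seed, "community"))
  n <- config$n_bins
  compounds <- c(.aa_by_cost, .vitamins)[seq_len(config$n_compounds)]
  classes <- rep(c("amino_acid", "vitamin"),
                 c(length(.aa_by_cost), length(.vitamins)))[seq_len(config$n_compounds)]

  pathways <- lapply(seq_along(compounds), function(ci) {
    n_steps <- sample(config$steps_per_pathway[1]:config$steps_per_pathway[2], 1L)
    steps <- lapply(seq_len(n_steps), function(si) {
      k <- sample(config$or_group_size[1]:config$or_group_size[2], 1L)
      sprintf("K%02d%02d%d", ci, si, seq_len(k))
    })
    pathway_definition(compounds[ci], classes[ci], steps,
                       transporter_relevant =
                         !(compounds[ci] %in% .no_transporter_needed),
                       cost_rank = ci)
  })
  names(pathways) <- compounds

  bin_ids <- sprintf("Bin%02d", seq_len(n))
  sizes <- round(stats::runif(n, 1e6, 6e6))
  completeness <- stats::runif(n, 0.86, 0.99)
  contamination <- stats::runif(n, 0, 0.03)
  abundance <- stats::rgamma(n, shape = 2, rate = 1)
  abundance <- abundance / sum(abundance)
  activity <- stats::rlnorm(n, 0, 0.75)
  names(abundance) <- names(activity) <- bin_ids

  background_pool <- sprintf("H%04d", seq_len(200L))
  base_pathway_fpkm <- 50
  base_background_fpkm <- 10

  status <- matrix("prototroph", n, length(compounds),
                   dimnames = list(bin_ids, compounds))
  # expression multiplier applied to a bin's genes of one pathway
  expr_factor <- matrix(1, n, length(compounds),
                        dimnames = list(bin_ids, compounds))
  bin_genes <- stats::setNames(vector("list", n), bin_ids)
  for (i in seq_len(n)) bin_genes[[i]] <- sample(background_pool, 50L)

  for (ci in seq_along(compounds)) {
    pw <- pathways[[ci]]
    n_steps <- length(pw$steps)
    for (i in seq_len(n)) {
      u <- stats::runif(1)
      if (u < config$auxotroph_rate) {
        status[i, ci] <- "auxotroph"
        low_expr <- stats::runif(1) < config$low_expression_auxotroph_rate
        n_missing <- if (low_expr || n_steps < 2L) 1L
                     else sample(2:min(3L, n_steps), 1L)
        if (low_expr) expr_factor[i, ci] <- config$low_expression_factor
      } else {
        smp <- stats::runif(1) < config$single_missing_prototroph_rate
        n_missing <- if (smp) 1L else 0L
      }
      if (status[i, ci] == "auxotroph" && n_missing < 1L) n_missing <- 1L
      missing <- if (n_missing > 0L) sample.int(n_steps, n_missing) else integer()
      present_steps <- setdiff(seq_len(n_steps), missing)
      genes <- unlist(lapply(present_steps, function(si) {
        g <- pw$steps[[si]]
        keep <- stats::runif(length(g)) < 0.7
        if (!any(keep)) keep[sample.int(length(g), 1L)] <- TRUE
        g[keep]
      }))
      bin_genes[[i]] <- c(bin_genes[[i]], genes)
    }
  }

  transporter_relevant <- compounds[vapply(pathways, `[[`, TRUE,
                                           "transporter_relevant")]
  bins <- lapply(seq_len(n), function(i) {
    tr <- transporter_relevant[stats::runif(length(transporter_relevant)) < 0.5]
    genome_bin(bin_ids[i], taxonomy = sprintf("Synthetic taxon %d", i),
               genome_size = sizes[i], completeness = completeness[i],
               contamination = contamination[i],
               genes = bin_genes[[i]], transporters = tr)
  })

  # per-(bin, gene) lengths and expected FPKM
  gene_df <- do.call(rbind, lapply(seq_len(n), function(i) {
    g <- sort(unique(bin_genes[[i]]))
    data.frame(bin_id = bin_ids[i], gene_id = g,
               length_bp = sample(300:3000, length(g), replace = TRUE),
               stringsAsFactors = FALSE)
  }))
  pathway_of_gene <- stats::setNames(
    rep(seq_along(compounds),
        vapply(pathways, function(p) length(unlist(p$steps)), 1L)),
    unlist(lapply(pathways, function(p) unlist(p$steps))))
  ci_of <- pathway_of_gene[gene_df$gene_id]            # NA for background
  base <- ifelse(is.na(ci_of), base_background_fpkm, base_pathway_fpkm)
  factor_of <- ifelse(is.na(ci_of), 1,
                      expr_factor[cbind(gene_df$bin_id,
                                        compounds[ifelse(is.na(ci_of), 1L, ci_of)])])
  noise <- if (config$expression_noise_sd > 0)
    stats::rlnorm(nrow(gene_df), 0, config$expression_noise_sd) else 1
  expressed_mean <- data.frame(bin_id = gene_df$bin_id,
                               gene_id = gene_df$gene_id,
                               mean_fpkm = base * factor_of * noise,
                               stringsAsFactors = FALSE)

  truth <- list(
    status_truth = data.frame(
      bin_id = rep(bin_ids, times = length(compounds)),
      compound_id = rep(compounds, each = n),
      status = as.vector(status),
      stringsAsFactors = FALSE),
    abundance_truth = abundance,
    activity_truth = activity,
    expressed_mean = expressed_mean)

  list(community = community(bins,
                             gene_records(gene_df$gene_id, gene_df$bin_id,
                                          gene_df$length_bp),
                             pathways),
       truth = truth, config = config)
}

#' Simulate DNA and cDNA read-mapping summaries
#'
#' DNA reads are a multinomial draw with cell probabilities proportional to
#' abundance x genome size (plus an unmapped cell); cDNA reads use
#' abundance x genome size x activity, so the expected cDNA/DNA mapping-rate
#' ratio of a bin is proportional to its activity multiplier (activity is a
#' per-base-pair transcription multiplier). Deterministic given the config
#' seed.
#'
#' @param truth Truth list from [generate_community()].
#' @param comm The matching [community()].
#' @param config The [generator_config()].
#' @param sample_id Sample label.
#' @return List with elements \code{dna} and \code{cdna}, each a
#'   [read_mapping_summary()].
#' @export
simulate_mapping <- function(truth, comm, config, sample_id = "sim") {
  stopifnot(inherits(config, "generator_config"))
  set.seed(.stage_seed(config$seed, "mapping"))
  sizes <- vapply(comm$bins, `[[`, 1, "genome_size")
  ids <- names(comm$bins)
  a <- truth$abundance_truth[ids]
  act <- truth$activity_truth[ids]
  draw <- function(weights, depth) {
    p <- weights / sum(weights) * (1 - config$unmapped_fraction)
    counts <- stats::rmultinom(1, depth, c(p, config$unmapped_fraction))[, 1]
    stats::setNames(counts[seq_along(ids)], ids)
  }
  list(
    dna = read_mapping_summary(sample_id, "DNA", config$dna_depth,
                               draw(a * sizes, config$dna_depth)),
    cdna = read_mapping_summary(sample_id, "cDNA", config$cdna_depth,
                                draw(a * sizes * act, config$cdna_depth))
  )
}

#' Simulate fragment counts and build the expression table
#'
#' Fragment counts per present gene are Poisson with mean
#' \code{expected FPKM x (length/1000) x (depth/1e6)}, so FPKM computed via
#' [fpkm()] recovers the planted expectation; genes of absent pathway steps
#' have no gene record in the bin and therefore no fragments. With
#' \code{count_noise = FALSE} the Poisson draw is replaced by its mean and
#' FPKM equals the planted expectation exactly. Deterministic given the
#' config seed.
#'
#' @inheritParams simulate_mapping
#' @return An [expression_table()].
#' @export
simulate_expression <- function(truth, comm, config, sample_id = "sim") {
  stopifnot(inherits(config, "generator_config"))
  set.seed(.stage_seed(config$seed, "expression"))
  em <- truth$expressed_mean
  genes <- comm$genes
  hit <- match(paste(em$bin_id, em$gene_id, sep = "\r"),
               paste(genes$bin_id, genes$gene_id, sep = "\r"))
  if (anyNA(hit))
    stop("expressed_mean refers to a gene without a gene record", call. = FALSE)
  lambda <- em$mean_fpkm * (genes$length_bp[hit] / 1000) *
    (config$cdna_depth / 1e6)
  frags <- if (config$count_noise) stats::rpois(length(lambda), lambda) else lambda
  counts <- data.frame(bin_id = em$bin_id, gene_id = em$gene_id,
                       fragments = frags, stringsAsFactors = FALSE)
  counts <- counts[order(counts$bin_id, counts$gene_id), , drop = FALSE]
  rownames(counts) <- NULL
  out <- fpkm(counts, genes, config$cdna_depth, sample_id = sample_id)
  attr(out, "fragments") <- counts
  out
}

#' Run all generator stages and write them to a directory
#'
#' Emits the community files (\code{bins.tsv}, \code{genes.tsv},
#' \code{pathways.json}), \code{mapping.tsv}, \code{expression.tsv} +
#' \code{totals.tsv}, and \code{truth.json}. Output is byte-identical for
#' identical configs.
#'
#' @param config A [generator_config()].
#' @param dir_path Output directory.
#' @return Invisibly, the list from [generate_community()] plus
#'   \code{mapping} and \code{expression}.
#' @export
simulate_to_dir <- function(config, dir_path) {
  sim <- generate_community(config)
  mapping <- simulate_mapping(sim$truth, sim$community, config)
  expr <- simulate_expression(sim$truth, sim$community, config)
  dir.create(dir_path, recursive = TRUE, showWarnings = FALSE)
  write_community(sim$community, dir_path)
  write_mapping(mapping, file.path(dir_path, "mapping.tsv"))
  write_fragment_counts(
    stats::setNames(
      list(list(fragments = attr(expr, "fragments"),
                total_mapped_fragments = expr$total_mapped_fragments)),
      expr$sample_id),
    file.path(dir_path, "expression.tsv"),
    file.path(dir_path, "totals.tsv"))
  jsonlite::write_json(
    list(status_truth = sim$truth$status_truth,
         abundance_truth = as.list(sim$truth$abundance_truth),
         activity_truth = as.list(sim$truth$activity_truth),
         expressed_mean = sim$truth$expressed_mean),
    file.path(dir_path, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(c(sim, list(mapping = mapping, expression = expr)))
}
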