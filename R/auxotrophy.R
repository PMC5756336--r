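# Auxotrophy calling from pathway-step completeness. Counting is step-level,
# not gene-level: an OR-group (isoenzymes for one reaction) with any member
# present is satisfied, so alternative enzymes never create false
# auxotrophies. The call rule: two or more missing steps confirm auxotrophy;
# a single missing step may be rescued when the rest of the pathway is
# transcribed at a level similar to or higher than in bins carrying the
# complete pathway (a single absent gene in an otherwise expressed pathway is
# more likely a binning/assembly gap than a true loss).

#' Evaluate pathway completeness in one bin
#'
#' A step is satisfied iff at least one gene of its OR-group is in the bin's
#' gene inventory. When an expression table is supplied, the pathway's
#' expression score is the median FPKM over the pathway genes present in the
#' bin (genes absent from the table count as 0 FPKM).
#'
#' @param bin A [genome_bin()].
#' @param pathway A [pathway_definition()].
#' @param expression Optional [expression_table()].
#' @return Object of class \code{pathway_evaluation}: bin_id, compound_id,
#'   missing_steps (integer indices), expression_score (NA without
#'   expression data), reference_scores (filled by [auxotrophy_matrix()]).
#' @export
pathway_completeness <- function(bin, pathway, expression = NULL) {
  stopifnot(inherits(bin, "genome_bin"), inherits(pathway, "pathway_definition"))
  satisfied <- vapply(pathway$steps, function(g) any(g %in% bin$genes), TRUE)
  score <- NA_real_
  if (!is.null(expression)) {
    stopifnot(inherits(expression, "expression_table"))
    present <- intersect(unlist(pathway$steps), bin$genes)
    if (length(present)) {
      ev <- expression$values
      sub <- ev$fpkm[ev$bin_id == bin$bin_id & ev$gene_id %in% present]
      vals <- c(sub, rep(0, length(present) - length(sub)))
      score <- stats::median(vals)
    } else {
      score <- 0
    }
  }
  structure(
    list(bin_id = bin$bin_id, compound_id = pathway$compound_id,
         missing_steps = which(!satisfied),
         expression_score = score,
         reference_scores = numeric(0)),
    class = "pathway_evaluation"
  )
}

#' Expression-rescue test for a single-gap pathway
#'
#' For a pathway with exactly one missing step, decides whether the observed
#' pathway expression is "similar or higher" than in reference bins that
#' carry the complete pathway: rescued iff
#' \code{expression_score >= alpha * median(reference_scores)} with
#' non-empty references. \code{alpha} below 1 encodes "similar".
#'
#' @param eval A \code{pathway_evaluation} with exactly one missing step and
#'   an expression score.
#' @param alpha Similarity tolerance in (0, 1]; default 0.75.
#' @return \code{TRUE} if rescued, \code{FALSE} otherwise (including when no
#'   reference bin exists; callers treat the empty-reference case as
#'   indeterminate).
#' @export
expression_rescue <- function(eval, alpha = 0.75) {
  stopifnot(inherits(eval, "pathway_evaluation"))
  if (length(eval$missing_steps) != 1L)
    stop("expression_rescue applies only to pathways with exactly 1 missing step (got ",
         length(eval$missing_steps), ")", call. = FALSE)
  if (is.na(eval$expression_score))
    stop("expression_rescue requires an expression score", call. = FALSE)
  length(eval$reference_scores) > 0L &&
    eval$expression_score >= alpha * stats::median(eval$reference_scores)
}

#' Call prototrophy/auxotrophy for one bin and compound
#'
#' Decision rule: 0 missing steps is a prototroph; 2 or more missing steps an
#' auxotroph regardless of expression; exactly 1 missing step is a prototroph
#' when the expression-rescue test passes, an auxotroph when it evaluably
#' fails, and indeterminate when no expression data or no complete-pathway
#' reference bin is available. Transporter presence is recorded (NA when the
#' compound needs no transporter) but never changes the status.
#'
#' @param eval \code{pathway_evaluation} (with \code{reference_scores} set).
#' @param pathway The matching [pathway_definition()].
#' @param bin The matching [genome_bin()].
#' @param expression_available Logical; was expression data supplied?
#' @param alpha Rescue tolerance, see [expression_rescue()].
#' @return One-row data.frame: bin_id, compound_id, status, n_missing_steps,
#'   rescue_applied, pathway_expression_score, transporter_present,
#'   cost_rank.
#' @export
call_auxotrophy <- function(eval, pathway, bin, expression_available,
                            alpha = 0.75) {
  n_missing <- length(eval$missing_steps)
  rescue_applied <- FALSE
  if (n_missing == 0L) {
    status <- "prototroph"
  } else if (n_missing >= 2L) {
    status <- "auxotroph"
  } else if (!expression_available || is.na(eval$expression_score)) {
    status <- "indeterminate"
  } else if (length(eval$reference_scores) == 0L) {
    status <- "indeterminate"
  } else if (expression_rescue(eval, alpha)) {
    status <- "prototroph"
    rescue_applied <- TRUE
  } else {
    status <- "auxotroph"
  }
  transporter <- if (!pathway$transporter_relevant) NA
                 else pathway$compound_id %in% bin$transporters
  data.frame(bin_id = eval$bin_id, compound_id = eval$compound_id,
             status = status, n_missing_steps = n_missing,
             rescue_applied = rescue_applied,
             pathway_expression_score = eval$expression_score,
             transporter_present = transporter,
             cost_rank = pathway$cost_rank,
             stringsAsFactors = FALSE)
}

#' Auxotrophy calls over a complete bins-by-compounds grid
#'
#' Evaluates every pathway in every bin. For each pathway, the reference
#' expression scores are those of bins with zero missing steps; single-gap
#' bins are then rescued or confirmed against that reference. Output order
#' is deterministic: cost_rank, then compound_id, then bin_id, regardless of
#' input order.
#'
#' @param bins List of [genome_bin()] objects (or a [community()]).
#' @param pathways List of [pathway_definition()] objects (ignored when a
#'   community is given).
#' @param expression Optional [expression_table()].
#' @param alpha Rescue tolerance.
#' @return data.frame of calls, one row per bin x compound.
#' @export
auxotrophy_matrix <- function(bins, pathways = NULL, expression = NULL,
                              alpha = 0.75) {
  if (inherits(bins, "community")) {
    pathways <- bins$pathways
    bins <- bins$bins
  }
  ids <- vapply(bins, `[[`, "", "bin_id")
  bins <- bins[order(ids)]
  rk <- vapply(pathways, `[[`, 1L, "cost_rank")
  cid <- vapply(pathways, `[[`, "", "compound_id")
  pathways <- pathways[order(rk, cid)]
  expression_available <- !is.null(expression)
  rows <- lapply(pathways, function(pw) {
    evals <- lapply(bins, pathway_completeness, pathway = pw,
                    expression = expression)
    refs <- unlist(lapply(evals, function(e)
      if (length(e$missing_steps) == 0L && !is.na(e$expression_score))
        e$expression_score else NULL))
    if (is.null(refs)) refs <- numeric(0)
    do.call(rbind, lapply(seq_along(bins), function(i) {
      e <- evals[[i]]
      e$reference_scores <- refs
      call_auxotrophy(e, pw, bins[[i]], expression_available, alpha)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Community-level compound coverage
#'
#' A compound is covered when at least one bin in the community is a
#' prototroph for it: the community "taken as a unit" can synthesize it and
#' cross-feeding can supply auxotrophic members. Compounds whose only
#' non-auxotroph calls are indeterminate are uncovered but flagged as
#' data-limited.
#'
#' @param calls Complete call grid from [auxotrophy_matrix()].
#' @return data.frame with columns compound_id, covered, data_limited.
#' @export
community_complementarity <- function(calls) {
  stopifnot(is.data.frame(calls))
  sp <- split(calls, calls$compound_id)
  out <- do.call(rbind, lapply(sp, function(g) {
    data.frame(compound_id = g$compound_id[1L],
               covered = any(g$status == "prototroph"),
               data_limited = !any(g$status == "prototroph") &&
                 any(g$status == "indeterminate"),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$compound_id), , drop = FALSE]
}
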