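test_that("a step is satisfied iff any OR-group member is present", {
  pw <- pathway_definition("x", "amino_acid", steps = list(c("g1", "g2")))
  # brute force over all four presence subsets of {g1, g2}
  for (g1 in c(TRUE, FALSE)) for (g2 in c(TRUE, FALSE)) {
    bin <- genome_bin("B", genome_size = 1e6,
                      genes = c("g1", "g2")[c(g1, g2)])
    ev <- pathway_completeness(bin, pw)
    expect_equal(length(ev$missing_steps) == 0L, g1 || g2)
  }
})

test_that("missing steps are counted at step level, not gene level", {
  pw <- pathway_definition("x", "amino_acid",
                           steps = list(c("a1", "a2"), "b1", c("c1", "c2")))
  bin <- genome_bin("B", genome_size = 1e6, genes = "a2")
  ev <- pathway_completeness(bin, pw)
  expect_equal(ev$missing_steps, c(2L, 3L))
  full <- genome_bin("B", genome_size = 1e6, genes = c("a1", "b1", "c1"))
  expect_length(pathway_completeness(full, pw)$missing_steps, 0L)
})

test_that("expression rescue encodes 'similar or higher' against references", {
  # score equal to the reference median counts as similar -> rescued
  expect_true(expression_rescue(make_eval(missing = 1L, score = 5,
                                          refs = c(4, 5, 6))))
  # zero expression against positive references is not rescued
  expect_false(expression_rescue(make_eval(missing = 1L, score = 0,
                                           refs = c(4, 5, 6))))
  # no complete-pathway reference: not rescued (caller marks indeterminate)
  expect_false(expression_rescue(make_eval(missing = 1L, score = 5,
                                           refs = numeric())))
  # just below alpha x median fails; at alpha x median passes
  expect_false(expression_rescue(make_eval(missing = 1L, score = 3.74,
                                           refs = 5)))
  expect_true(expression_rescue(make_eval(missing = 1L, score = 3.75,
                                          refs = 5)))
  expect_error(expression_rescue(make_eval(missing = c(1L, 2L), score = 5)),
               "exactly 1 missing step")
  expect_error(expression_rescue(make_eval(missing = integer(), score = 5)),
               "exactly 1 missing step")
})

test_that("call_auxotrophy matches the exhaustive decision table", {
  pw <- pathway_definition("lysine", "amino_acid",
                           steps = list("s1", "s2", "s3"), cost_rank = 1L)
  bin <- genome_bin("B", genome_size = 1e6)
  cases <- expand.grid(n_missing = 0:2,
                       rescue = c("true", "false", "unavailable"),
                       stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cases))) {
    nm <- cases$n_missing[i]
    rescue <- cases$rescue[i]
    ev <- make_eval(missing = seq_len(nm),
                    score = switch(rescue, true = 10, false = 1,
                                   unavailable = NA_real_),
                    refs = if (rescue == "unavailable") numeric() else 10)
    expression_available <- !is.na(ev$expression_score)
    call <- call_auxotrophy(ev, pw, bin, expression_available)
    expect_equal(call$status, oracle_call_status(nm, rescue),
                 label = sprintf("missing=%d rescue=%s", nm, rescue))
    expect_equal(call$rescue_applied, nm == 1L && rescue == "true")
  }
  # the second indeterminate route: expression present but no reference bins
  ev <- make_eval(missing = 1L, score = 10, refs = numeric())
  expect_equal(call_auxotrophy(ev, pw, bin, TRUE)$status, "indeterminate")
})

test_that("transporter flag is recorded but never changes the status", {
  no_tr <- pathway_definition("B2", "vitamin", steps = list("v1"),
                              transporter_relevant = FALSE, cost_rank = 2L)
  tr <- pathway_definition("B12", "vitamin", steps = list("w1"),
                           transporter_relevant = TRUE, cost_rank = 3L)
  bin <- genome_bin("B", genome_size = 1e6, genes = c("v1", "w1"),
                    transporters = "B12")
  ev1 <- pathway_completeness(bin, no_tr)
  ev2 <- pathway_completeness(bin, tr)
  c1 <- call_auxotrophy(ev1, no_tr, bin, FALSE)
  c2 <- call_auxotrophy(ev2, tr, bin, FALSE)
  expect_true(is.na(c1$transporter_present))   # not applicable for B2
  expect_true(c2$transporter_present)
  expect_equal(c(c1$status, c2$status), rep("prototroph", 2))
})

test_that("adding genes never turns a prototroph into an auxotroph", {
  set.seed(55)
  for (i in 1:30) {
    n_steps <- sample(2:5, 1)
    pw <- pathway_definition("x", "amino_acid",
                             steps = lapply(seq_len(n_steps), function(s)
                               sprintf("s%d_%d", s, seq_len(sample(1:3, 1)))))
    all_genes <- unlist(pw$steps)
    g0 <- sample(all_genes, sample(0:length(all_genes), 1))
    bin0 <- genome_bin("B", genome_size = 1e6, genes = g0)
    extra <- sample(setdiff(all_genes, g0),
                    sample(0:length(setdiff(all_genes, g0)), 1))
    bin1 <- genome_bin("B", genome_size = 1e6, genes = c(g0, extra))
    s0 <- call_auxotrophy(pathway_completeness(bin0, pw), pw, bin0, FALSE)$status
    s1 <- call_auxotrophy(pathway_completeness(bin1, pw), pw, bin1, FALSE)$status
    if (s0 == "prototroph") expect_equal(s1, "prototroph")
  }
})

test_that("the call grid is complete and canonically ordered", {
  sim <- generate_community(generator_config(n_bins = 7L, n_compounds = 29L,
                                             seed = 19L))
  calls <- auxotrophy_matrix(sim$community)
  expect_equal(nrow(calls), 7L * 29L)   # 20 amino acids + 9 vitamins
  expect_equal(calls$cost_rank, sort(calls$cost_rank))
  shuffled <- auxotrophy_matrix(rev(unname(sim$community$bins)),
                                rev(unname(sim$community$pathways)))
  expect_identical(shuffled, auxotrophy_matrix(unname(sim$community$bins),
                                               unname(sim$community$pathways)))
  # without expression data every single-gap pathway is indeterminate
  expect_true(all(calls$status[calls$n_missing_steps == 1L] == "indeterminate"))
})

test_that("community complementarity follows prototroph coverage", {
  mk <- function(statuses, compound) {
    data.frame(bin_id = sprintf("B%d", seq_along(statuses)),
               compound_id = compound, status = statuses,
               n_missing_steps = 0L, rescue_applied = FALSE,
               pathway_expression_score = NA_real_, transporter_present = NA,
               cost_rank = 1L, stringsAsFactors = FALSE)
  }
  calls <- rbind(mk(c("auxotroph", "auxotroph"), "B12"),
                 mk(c("prototroph", "auxotroph"), "histidine"),
                 mk(c("indeterminate", "auxotroph"), "B7"))
  cc <- community_complementarity(calls)
  row <- function(id) cc[cc$compound_id == id, ]
  expect_false(row("B12")$covered)
  expect_false(row("B12")$data_limited)
  expect_true(row("histidine")$covered)
  expect_true(row("B7")$data_limited)
  expect_false(row("B7")$covered)
})

test_that("noiseless synthetic communities are recovered exactly", {
  cfg <- generator_config(n_bins = 8L, n_compounds = 8L,
                          expression_noise_sd = 0, count_noise = FALSE,
                          seed = 23L)
  sim <- generate_community(cfg)
  expr <- simulate_expression(sim$truth, sim$community, cfg)
  calls <- auxotrophy_matrix(sim$community, expression = expr)
  m <- merge(calls, sim$truth$status_truth, by = c("bin_id", "compound_id"))
  expect_equal(nrow(m), 64L)
  expect_true(all(m$status.x == m$status.y))
})
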