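# Independent oracles, deliberately coded apart from the package internals.

# Gibbs energy by plain spreadsheet-style arithmetic: sum of nu * Gf, then a
# multiplicative reaction quotient, van't Hoff adjustment written out long-hand.
oracle_delta_g <- function(rxn, cond, table = formation_energy_table()) {
  g0 <- 0
  h0 <- 0
  Q <- 1
  for (sp in names(rxn$stoichiometry)) {
    nu <- rxn$stoichiometry[[sp]]
    row <- table[table$species == sp, ]
    g0 <- g0 + nu * row$dGf0
    h0 <- h0 + nu * row$dHf0
    act <- if (rxn$phases[[sp]] %in% c("water", "pure_liquid")) 1
           else if (sp == "H+") 10^(-cond$pH)
           else if (rxn$phases[[sp]] == "aqueous") unname(cond$concentrations[sp])
           else unname(cond$partial_pressures[sp])
    Q <- Q * act^nu
  }
  T0 <- 298.15
  if (abs(cond$temperature - T0) > 1e-9)
    g0 <- h0 + (g0 - h0) * cond$temperature / T0
  g0 + 8.314e-3 * cond$temperature * log(Q)
}

# Closed-form equilibrium acetate: dG(acetate = 1 M) + nu*RT*ln(a) = 0.
oracle_eq_acetate <- function(rxn, cond, table = formation_energy_table()) {
  nu <- rxn$stoichiometry[["acetate"]]
  cond$concentrations["acetate"] <- 1
  g_at_1 <- oracle_delta_g(rxn, cond, table)
  exp(-g_at_1 / (nu * 8.314e-3 * cond$temperature))
}

.cond_with_acetate <- function(cond, a) {
  cond$concentrations["acetate"] <- a
  cond
}

# Exhaustive decision table for the auxotrophy call,
# (missing steps) x (rescue outcome) -> status.
oracle_call_status <- function(n_missing, rescue) {
  if (n_missing == 0) return("prototroph")
  if (n_missing >= 2) return("auxotroph")
  switch(rescue,
         true = "prototroph",
         false = "auxotroph",
         unavailable = "indeterminate")
}

# Top-quantile flagging by explicit sort-and-count.
oracle_flagged <- function(values, q = 0.75) {
  s <- sort(values)
  thr <- s[ceiling(q * length(s))]
  which(values > thr)
}

# Hand-build a pathway_evaluation without going through the constructors.
make_eval <- function(bin_id = "B1", compound_id = "lysine",
                      missing = integer(), score = NA_real_,
                      refs = numeric()) {
  structure(list(bin_id = bin_id, compound_id = compound_id,
                 missing_steps = missing, expression_score = score,
                 reference_scores = refs),
            class = "pathway_evaluation")
}

# Small fixture community built in code: 3 bins, 10 genes, 2 pathways.
make_fixture_community <- function() {
  pw1 <- pathway_definition("lysine", "amino_acid",
                            steps = list(c("K1", "K2"), "K3", "K4"),
                            cost_rank = 1L)
  pw2 <- pathway_definition("B12", "vitamin",
                            steps = list("K5", c("K6", "K7")),
                            transporter_relevant = TRUE, cost_rank = 2L)
  b1 <- genome_bin("BinA", "Taxon a", 2.1e6, 0.95, 0.01,
                   genes = c("K1", "K3", "K4", "K5", "K6", "H1"),
                   transporters = "B12")
  b2 <- genome_bin("BinB", "Taxon b", 3.4e6, 0.9, 0.02,
                   genes = c("K2", "K3", "K4", "H2"))
  b3 <- genome_bin("BinC", "Taxon c", 1.2e6, 0.88, 0.005,
                   genes = c("K5", "K7", "H1", "H3"), transporters = "lysine")
  genes <- gene_records(
    gene_id = c("K1", "K3", "K4", "K5", "K6", "H1", "K2", "K3", "K4", "H2"),
    bin_id = c(rep("BinA", 6), rep("BinB", 4)),
    length_bp = c(900, 1200, 600, 1500, 300, 2100, 800, 1100, 450, 999))
  community(list(b1, b2, b3), genes, list(pw1, pw2))
}
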