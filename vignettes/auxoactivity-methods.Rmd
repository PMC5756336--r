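---
title: "Methods: activity, auxotrophy and bioenergetics of genome-resolved communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: activity, auxotrophy and bioenergetics of genome-resolved communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(auxoactivity)
```

## Scope and motivation

Oil reservoirs under secondary recovery host mixed aerobic/anaerobic
communities in which a large fraction of organisms detected by DNA sequencing
arrive with injection water and are metabolically inactive in situ. Paired
metagenome (DNA) and metatranscriptome (cDNA) sequencing separates the
standing community from its active members, and genome-resolved annotation
lets one ask which members can build their own amino acids and vitamins and
which depend on neighbours. `auxoactivity` implements the downstream,
quantitative part of such a study as reusable, tested functions. It
deliberately consumes *tabular* summaries — bins with quality metrics and
gene inventories, per-library mapped-read counts, per-gene fragment counts —
and leaves read QC, assembly, binning, annotation and alignment to the
dedicated upstream tools whose outputs those tables represent.

## Activity profiling

**Relative abundance.** Mapped-read counts scale with both cell abundance and
genome size, so per-bin counts are divided by genome size before
normalization:
\[ a_i = \frac{m_i / L_i}{\sum_j m_j / L_j}. \]
The vector sums to one over the mapped bins and is invariant under uniform
depth scaling; both properties are enforced by tests.

**cDNA/DNA ratio.** Within each library, a bin's mapping rate is mapped reads
over *total library reads* (using total reads, rather than total binned
reads, makes the denominator independent of how much of the community was
successfully binned). The activity ratio is the cDNA rate over the DNA rate,
and a bin is called active when the ratio strictly exceeds 0.5 — the
conventional cutoff for this assay; the strict inequality means a bin sitting
exactly at the threshold is inactive. Bins with zero DNA rate get an
undefined (`NA`) ratio, never infinity, and are never active. Whether the
upstream mapping used whole bins or only coding sequences as cDNA targets is
an upstream property; the package computes both rates against the same target
set given in the mapping table and records that scope in the output's
`target_scope` attribute.

## Expression classes

FPKM is computed as fragments / ((length/1000) × (total/10^6)). The
"highly transcribed" class takes the empirical 75th percentile of *all* FPKM
values in the sample (one cumulative distribution for the whole
metatranscriptome, not per bin) and flags genes strictly above it. The
quantile uses the lower nearest-rank convention (R's `quantile` type 1):
on `n` values the threshold is the `ceiling(0.75 n)`-th order statistic, so
the "top 25%" is an exact count on integer ranks and ties at the threshold
are not flagged. No interpolated quantile definition was adopted because the
flagged set should always correspond to an integer number of ranked genes.

## Auxotrophy calling

Pathways are ordered steps; each step is an OR-group of isoenzyme gene
identifiers. Completeness is counted at *step* level: a step with any member
present is satisfied, so alternative enzymes for one reaction cannot create
false auxotrophies. The call rule per bin × compound:

* 0 missing steps → prototroph;
* ≥ 2 missing steps → auxotroph, regardless of expression;
* exactly 1 missing step → decided by the expression-rescue test.

The rescue test reflects the observation that a single absent gene in an
otherwise actively transcribed pathway is more often an assembly or binning
gap than a true loss. "Overall transcription level" of a pathway is
operationalized as the **median FPKM of its present genes** (robust to one
outlier gene; the aggregate is otherwise unspecified in common practice), and
"similar or higher than bins with a complete pathway" as
`score >= alpha * median(reference scores)` with `alpha = 0.75` by default
(configurable). An `alpha` below 1 encodes "similar"; 1.0 would demand
"at least as high". When no expression data or no complete-pathway reference
bin exists the rule is inapplicable and the call is `indeterminate` rather
than forced either way.

Transporter presence is recorded next to each call (and `NA` for compounds
that need no dedicated uptake system, vitamins B2 and B3) but never changes
the status: transporters are displayed evidence of potential uptake, not part
of the biosynthesis rule. Genome incompleteness is likewise reported through
the bin's metadata but does not modify calls — a probabilistic correction for
missed genes would be an extension, not part of this rule set.

`community_complementarity()` summarizes the grid: a compound is covered when
at least one bin is a prototroph for it, the community "taken as a unit";
compounds whose only non-auxotroph calls are indeterminate are flagged
data-limited.

## Thermodynamic feasibility window

The bioenergetics module evaluates \( \Delta G = \Delta G^\circ(T) + RT\ln Q \)
with ideal dilute-solution activities (molar concentrations, coefficient 1),
partial pressures in atm, activity 1 for water and for hexadecane treated as
an excess pure oil phase, and \(a_{H^+} = 10^{-pH}\). Away from 298.15 K,
\(\Delta G^\circ\) is adjusted by the Gibbs–Helmholtz relation with bundled
formation enthalpies (temperature-independent \(\Delta H^\circ\) assumed).
Every evaluation re-checks C/H/O and charge balance against the bundled
species-composition table.

The default reaction set is explicit, user-replaceable data:

* R1: C16H34 + 16 H2O → 8 CH3COO⁻ + 8 H⁺ + 17 H2 (fermentation to acetate + H2);
* R2: 4 H2 + 2 HCO3⁻ + H⁺ → CH3COO⁻ + 4 H2O (reductive acetogenesis);
* R1′ = R1 + 17/4 R2: the H2-free net reaction with acetate as sole
  fermentation product (the default "fermentation" curve — organisms running
  the reductive acetyl-CoA pathway internally need not excrete H2; R1 is
  provided for users who prefer the H2-explicit form);
* R3: CH3COO⁻ + H2O → CH4 + HCO3⁻ (acetoclastic methanogenesis).

Increasing acetate makes R1′ less favourable (acetate is its product) and R3
more favourable (its substrate), so at a given pH the two \(\Delta G = 0\)
loci bracket an interval of acetate concentrations — the *window of
opportunity* — where fermenters and acetoclastic methanogens can both
operate. `equilibrium_acetate()` finds each locus by bracketed root finding
over log concentration followed by Newton polishing (the derivative in log
space is exactly \(\nu_{ac} RT\)) to \(|\Delta G| < 10^{-6}\) kJ/mol;
`feasibility_window()` evaluates both energies over a pH × acetate grid and
`assess_well()` classifies a measured (pH, acetate) pair by the signs of the
two energies (strict `< 0`; a well exactly on a boundary is not feasible for
that reaction).

Defaults that the literature source of such calculations leaves open are
explicit configuration: T = 298.15 K, bicarbonate 10 mM, CH4 1 atm,
H2 10⁻⁴ atm. The formation-energy table uses the standard anaerobic
bioenergetics compilations; for liquid hexadecane, \(\Delta G_f^\circ\) =
+58.9 kJ/mol derived from the calorimetric enthalpy of formation of the pure
liquid (−456.1 kJ/mol) and third-law entropies. No claim is made to reproduce
any particular published curve numerically — the reactions, species data and
conditions are all data the user can replace.

## Synthetic data: what it emulates, and what it does not

`generate_community()` plants, per bin × compound, one of four cases:
complete-pathway prototroph; single-gap prototroph (one step absent, pathway
expressed at the normal level — an emulated binning gap, 10% of prototroph
calls by default); multi-gap auxotroph (≥ 2 steps removed); and
low-expression auxotroph (one step absent with remaining genes at 10% of the
normal level, 25% of auxotrophs by default, exercising the "low overall
transcription" route to an auxotrophy call). Auxotroph probability defaults
to 0.3 per pair. Genome sizes are uniform on 1–6 Mb, completeness 86–99%,
contamination 0–3% (the high-quality bin regime), abundances a normalized
Gamma(2) (Dirichlet) draw, and activity multipliers log-normal(0, 0.75).

Expected FPKM per present gene is a baseline (50 for pathway genes, 10 for a
housekeeping background of 50 genes per bin) times log-normal noise with
`expression_noise_sd` (default 0.5). Fragment counts are Poisson with mean
proportional to expected FPKM × gene length × depth — the minimal standard
model for count data; a config flag replaces the draw by its expectation for
exact noiseless tests. Expression means are deliberately *not* scaled by the
bin's activity multiplier: the rescue rule compares pathway expression across
bins, and per-bin activity scaling would make it confound activity with
pathway completeness — a real limitation of the rescue rule that users should
keep in mind.

Read-mapping summaries are multinomial draws: DNA cell probabilities
proportional to abundance × genome size, cDNA proportional to
abundance × genome size × activity, plus an unmapped remainder (default 0.3,
emulating the inactive injection-water fraction). Defining the activity
multiplier per base pair (so that the expected cDNA/DNA rate ratio is
proportional to activity for *any* genome-size vector) keeps the planted
truth directly comparable to the estimator's output; the alternative —
per-cell transcript totals independent of genome size — would make the ratio
confounded by genome size, which is an upstream normalization question, not
one this package can resolve.

Each generator stage draws from its own stream keyed by (seed, stage name),
so mapping or expression can be regenerated independently and all outputs are
byte-reproducible given the config.

What the generator does **not** emulate: sequence content and alignment
error, multi-mapping reads, uneven coverage within genomes, compositional
correlations between abundance and activity, contamination genes from other
bins, and incompleteness-driven gene loss (absent genes are planted by rule,
not by truncating assemblies). Passing recovery tests therefore show the
*rules* are implemented correctly and are statistically recoverable under the
planted model — not that the pipeline is robust to every failure mode of real
sequencing data.

## Numerical choices and problem sizes

Worked problem sizes in the test-suite and in `scripts/acceptance.R` were
chosen as the smallest sizes at which each statistical property is clearly
identified: recovery on 20 bins × 20 compounds (400 pairs; exact without
noise, seed-averaged accuracy with log-normal SD 0.5 noise across 10 seeds),
ratio estimation at multinomial depth 10⁶, flagged-fraction convergence at
10⁴ genes, and a 50 × 50 feasibility grid checked point-by-point against an
independently coded brute-force evaluation. Root finding uses bracketing
bounds of 10⁻¹² to 10² mol/L; ties and degenerate inputs (empty tables,
zero-read bins, all-equal FPKM) are defined behaviour covered by tests.

## Worked example

```{r example, eval = FALSE}
cfg <- generator_config(seed = 7)
sim <- generate_community(cfg)
mapping <- simulate_mapping(sim$truth, sim$community, cfg)
expr <- simulate_expression(sim$truth, sim$community, cfg)

abund <- relative_abundance(mapping$dna, sim$community$bins)
profiles <- classify_active(cdna_dna_ratio(mapping$cdna, mapping$dna))
calls <- auxotrophy_matrix(sim$community, expression = expr)
community_complementarity(calls)

rx <- default_reactions()
fw <- feasibility_window(rx$alkane_fermentation_acetate,
                         rx$acetoclastic_methanogenesis,
                         pH_grid = seq(4, 9, 0.1),
                         acetate_grid = 10^seq(-8, 0, 0.1))
plot(fw)
assess_well(7.1, 2e-4, rx$alkane_fermentation_acetate,
            rx$acetoclastic_methanogenesis)
```

## Known limitations

* The rescue rule needs complete-pathway reference bins; rare pathways in
  small communities yield `indeterminate` calls by design.
* Step-level counting assumes the OR-groups in the pathway definitions are
  correct; wrong isoenzyme groupings propagate directly into calls.
* The thermodynamic module treats carbonate as bicarbonate at a stated
  concentration (no speciation), fixes activity coefficients at 1, and
  assumes temperature-independent reaction enthalpy for the van't Hoff
  adjustment — the customary level of theory for this kind of feasibility
  argument, adequate for window placement, not for precise energetics in
  brines.
* FPKM equality with external estimators that use effective lengths is not
  claimed; the package computes textbook FPKM from its inputs.
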