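# Bioenergetics of syntrophic alkane degradation: Gibbs free energy of
# hexadecane fermentation to acetate and of acetoclastic methanogenesis under
# in-situ conditions, following the classic reaction-quotient treatment used
# for anaerobic hydrocarbon energetics (ideal dilute solution, activity
# coefficients 1, excess oil phase with unit activity). The "window of
# opportunity" is the region of (pH, acetate) space where both reactions are
# simultaneously exergonic, i.e. where fermenters and acetoclastic
# methanogens can operate as a syntrophic unit.

.R_KJ <- 8.314e-3   # gas constant, kJ mol^-1 K^-1
.T_REF <- 298.15

#' Standard formation energies of the bundled species
#'
#' Standard Gibbs energies and enthalpies of formation at 298.15 K
#' (kJ/mol; aqueous species at 1 M ideal dilute solution, gases at 1 atm)
#' from the standard compilations used in anaerobic bioenergetics, with
#' elemental composition and charge used for balance checking. The
#' hexadecane(l) value is derived from calorimetric enthalpy and third-law
#' entropy of the pure liquid. Replace or extend the table to evaluate other
#' reactions.
#'
#' @return data.frame with columns species, dGf0, dHf0, C, H, O, charge.
#' @export
formation_energy_table <- function() {
  data.frame(
    species = c("hexadecane", "water", "acetate", "H+", "H2", "CH4",
                "HCO3-", "CO2"),
    dGf0 = c(58.9, -237.18, -369.41, 0, 0, -50.75, -586.85, -394.36),
    dHf0 = c(-456.1, -285.83, -486.01, 0, 0, -74.81, -691.99, -393.51),
    C = c(16, 0, 2, 0, 0, 1, 1, 1),
    H = c(34, 2, 3, 1, 2, 4, 1, 0),
    O = c(0, 1, 2, 0, 0, 0, 3, 2),
    charge = c(0, 0, -1, 1, 0, 0, -1, 0),
    stringsAsFactors = FALSE
  )
}

#' Construct a reaction
#'
#' @param name Reaction name.
#' @param stoichiometry Named numeric vector of signed coefficients, products
#'   positive, reactants negative.
#' @param phases Named character vector over the same species, each one of
#'   \code{"aqueous"}, \code{"gas"}, \code{"pure_liquid"}, \code{"water"}.
#' @param reference Free-text provenance note.
#' @return Object of class \code{reaction}.
#' @export
reaction <- function(name, stoichiometry, phases, reference = "") {
  stoichiometry <- unlist(stoichiometry)
  phases <- unlist(phases)
  if (is.null(names(stoichiometry)) || is.null(names(phases)))
    stop("stoichiometry and phases must be named by species", call. = FALSE)
  if (!setequal(names(stoichiometry), names(phases)))
    stop("stoichiometry and phases must cover the same species", call. = FALSE)
  ok <- phases %in% c("aqueous", "gas", "pure_liquid", "water")
  if (!all(ok))
    stop("unknown phase '", phases[!ok][1L], "'", call. = FALSE)
  structure(list(name = name,
                 stoichiometry = stoichiometry,
                 phases = phases[names(stoichiometry)],
                 reference = reference),
            class = "reaction")
}

#' @export
print.reaction <- function(x, ...) {
  s <- x$stoichiometry
  side <- function(v) paste(sprintf("%s %s", format(abs(v)), names(v)),
                            collapse = " + ")
  cat(sprintf("<reaction> %s\n  %s -> %s\n", x$name,
              side(s[s < 0]), side(s[s > 0])))
  invisible(x)
}

#' Construct physicochemical conditions
#'
#' @param temperature Kelvin (> 0).
#' @param pH Dimensionless; sets the proton activity \eqn{10^{-pH}}.
#' @param concentrations Named mol/L for aqueous species.
#' @param partial_pressures Named atm for gas species.
#' @return Object of class \code{conditions}.
#' @export
conditions <- function(temperature = 298.15, pH = 7,
                       concentrations = c(acetate = 1e-4, `HCO3-` = 0.01),
                       partial_pressures = c(CH4 = 1, H2 = 1e-4)) {
  if (temperature <= 0) stop("temperature must be > 0 K", call. = FALSE)
  if (any(concentrations <= 0) || any(partial_pressures <= 0))
    stop("concentrations and partial pressures must be > 0", call. = FALSE)
  structure(list(temperature = temperature, pH = pH,
                 concentrations = unlist(concentrations),
                 partial_pressures = unlist(partial_pressures)),
            class = "conditions")
}

#' Bundled default reactions
#'
#' The Dolfing-style default set for alkane-based syntrophy, all
#' user-replaceable data:
#' \itemize{
#'   \item \code{alkane_fermentation_h2}:
#'     C16H34 + 16 H2O -> 8 CH3COO- + 8 H+ + 17 H2
#'   \item \code{homoacetogenesis}: 4 H2 + 2 HCO3- + H+ -> CH3COO- + 4 H2O
#'     (Wood-Ljungdahl acetogenesis from H2/CO2)
#'   \item \code{alkane_fermentation_acetate}: the H2-free net reaction
#'     (fermentation + 17/4 homoacetogenesis), hexadecane oxidized with
#'     acetate as sole fermentation product
#'   \item \code{acetoclastic_methanogenesis}:
#'     CH3COO- + H2O -> CH4 + HCO3-
#' }
#'
#' @return Named list of [reaction()] objects.
#' @export
default_reactions <- function() {
  r1 <- reaction(
    "alkane_fermentation_h2",
    c(hexadecane = -1, water = -16, acetate = 8, `H+` = 8, H2 = 17),
    c(hexadecane = "pure_liquid", water = "water", acetate = "aqueous",
      `H+` = "aqueous", H2 = "gas"),
    "hexadecane fermentation to acetate and hydrogen")
  r2 <- reaction(
    "homoacetogenesis",
    c(H2 = -4, `HCO3-` = -2, `H+` = -1, acetate = 1, water = 4),
    c(H2 = "gas", `HCO3-` = "aqueous", `H+` = "aqueous",
      acetate = "aqueous", water = "water"),
    "reductive acetogenesis from H2 and bicarbonate (Wood-Ljungdahl)")
  r1p <- combine_reactions(r1, r2, 1, 17 / 4,
                           name = "alkane_fermentation_acetate")
  r3 <- reaction(
    "acetoclastic_methanogenesis",
    c(acetate = -1, water = -1, CH4 = 1, `HCO3-` = 1),
    c(acetate = "aqueous", water = "water", CH4 = "gas",
      `HCO3-` = "aqueous"),
    "acetate cleavage to methane and bicarbonate")
  list(alkane_fermentation_h2 = r1,
       homoacetogenesis = r2,
       alkane_fermentation_acetate = r1p,
       acetoclastic_methanogenesis = r3)
}

#' Linear combination of two reactions
#'
#' Builds the net reaction \code{a * r1 + b * r2}; species whose net
#' coefficient vanishes are dropped.
#'
#' @param r1,r2 [reaction()] objects.
#' @param a,b Rational multipliers.
#' @param name Name for the combined reaction.
#' @return A [reaction()].
#' @export
combine_reactions <- function(r1, r2, a = 1, b = 1,
                              name = paste0(r1$name, "+", r2$name)) {
  species <- union(names(r1$stoichiometry), names(r2$stoichiometry))
  coef <- stats::setNames(numeric(length(species)), species)
  coef[names(r1$stoichiometry)] <- a * r1$stoichiometry
  coef[names(r2$stoichiometry)] <- coef[names(r2$stoichiometry)] +
    b * r2$stoichiometry
  phases <- c(r1$phases, r2$phases)
  phases <- phases[!duplicated(names(phases))]
  keep <- abs(coef) > 1e-12
  reaction(name, coef[keep], phases[species][keep],
           reference = sprintf("%g x (%s) + %g x (%s)",
                               a, r1$name, b, r2$name))
}

.check_balance <- function(reaction, table) {
  idx <- match(names(reaction$stoichiometry), table$species)
  if (anyNA(idx))
    stop("no formation-energy datum for species '",
         names(reaction$stoichiometry)[is.na(idx)][1L], "'", call. = FALSE)
  for (el in c("C", "H", "O", "charge")) {
    net <- sum(reaction$stoichiometry * table[[el]][idx])
    if (abs(net) > 1e-9)
      stop("reaction '", reaction$name, "' is not balanced in ",
           if (el == "charge") "charge" else paste("element", el),
           " (net ", format(net), ")", call. = FALSE)
  }
  idx
}

.ln_activity <- function(reaction, conditions) {
  vapply(names(reaction$stoichiometry), function(sp) {
    ph <- reaction$phases[[sp]]
    if (ph %in% c("water", "pure_liquid")) return(0)
    if (sp == "H+") return(-conditions$pH * log(10))
    if (ph == "aqueous") {
      a <- conditions$concentrations[sp]
      if (is.na(a)) stop("no concentration given for aqueous species '",
                         sp, "'", call. = FALSE)
      return(log(unname(a)))
    }
    p <- conditions$partial_pressures[sp]
    if (is.na(p)) stop("no partial pressure given for gas species '",
                       sp, "'", call. = FALSE)
    log(unname(p))
  }, 1)
}

#' Gibbs free energy of a reaction under given conditions
#'
#' \deqn{\Delta G = \Delta G^\circ(T) + RT \ln Q}
#' with \eqn{\Delta G^\circ = \sum_i \nu_i \Delta G_f^\circ{}_i}. Activities:
#' molar concentration for aqueous species (coefficient 1), partial pressure
#' in atm for gases, 1 for water and pure liquids, \eqn{10^{-pH}} for H+.
#' At temperatures other than 298.15 K, \eqn{\Delta G^\circ} is adjusted by
#' the Gibbs-Helmholtz (van't Hoff) relation using the bundled formation
#' enthalpies, assuming temperature-independent \eqn{\Delta H^\circ}.
#' Elemental (C, H, O) and charge balance are verified on every call.
#'
#' @param reaction A [reaction()].
#' @param conditions A [conditions()].
#' @param table Formation-energy table, default [formation_energy_table()].
#' @return Gibbs energy in kJ per mole of reaction; negative = exergonic.
#' @export
delta_g <- function(reaction, conditions, table = formation_energy_table()) {
  stopifnot(inherits(reaction, "reaction"), inherits(conditions, "conditions"))
  idx <- .check_balance(reaction, table)
  nu <- reaction$stoichiometry
  dg0 <- sum(nu * table$dGf0[idx])
  temp <- conditions$temperature
  if (abs(temp - .T_REF) > 1e-9) {
    dh0 <- sum(nu * table$dHf0[idx])
    dg0 <- dh0 * (1 - temp / .T_REF) + dg0 * (temp / .T_REF)
  }
  lnQ <- sum(nu * .ln_activity(reaction, conditions))
  dg0 + .R_KJ * temp * lnQ
}

.with_acetate <- function(conditions, acetate) {
  conditions$concentrations["acetate"] <- acetate
  conditions
}

#' Equilibrium acetate concentration of a reaction
#'
#' Solves \eqn{\Delta G = 0} for the acetate concentration by root finding
#' over log-concentration, then polishes with Newton steps (the derivative
#' is exactly \eqn{\nu_{acetate} RT} in log space) until
#' \eqn{|\Delta G| < 10^{-6}} kJ/mol. Requires acetate to appear on one side
#' of the reaction only, making \eqn{\Delta G} monotone in acetate.
#'
#' @param reaction A [reaction()] containing acetate.
#' @param conditions Base [conditions()]; its acetate entry is overridden.
#' @param table Formation-energy table.
#' @param bounds Search interval in mol/L.
#' @return Acetate concentration (mol/L) at which \eqn{\Delta G = 0}.
#' @export
equilibrium_acetate <- function(reaction, conditions,
                                table = formation_energy_table(),
                                bounds = c(1e-12, 1e2)) {
  nu <- reaction$stoichiometry["acetate"]
  if (is.na(nu) || nu == 0)
    stop("reaction '", reaction$name, "' does not involve acetate",
         call. = FALSE)
  f <- function(ln_a) delta_g(reaction, .with_acetate(conditions, exp(ln_a)),
                              table)
  lo <- log(bounds[1L]); hi <- log(bounds[2L])
  flo <- f(lo); fhi <- f(hi)
  if (sign(flo) == sign(fhi))
    stop("no sign change of delta G in bounds: dG(", bounds[1L], " M) = ",
         format(flo), ", dG(", bounds[2L], " M) = ", format(fhi),
         call. = FALSE)
  root <- stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
  slope <- unname(nu) * .R_KJ * conditions$temperature
  for (i in 1:4) root <- root - f(root) / slope
  stopifnot(abs(f(root)) < 1e-6)
  exp(root)
}

#' Feasibility window over a pH-by-acetate grid
#'
#' Evaluates the fermentation and methanogenesis Gibbs energies at every
#' grid point; a point is inside the window when both are strictly
#' exergonic. Boundary curves (the \eqn{\Delta G = 0} loci) are exported per
#' pH as the two equilibrium acetate concentrations (NA where no root lies
#' within the acetate grid span).
#'
#' @param fermentation,methanogenesis [reaction()] objects.
#' @param pH_grid Strictly increasing pH values.
#' @param acetate_grid Strictly increasing acetate concentrations (mol/L),
#'   typically log-spaced.
#' @param conditions_base Base [conditions()]; pH and acetate are overridden
#'   per grid point.
#' @param table Formation-energy table.
#' @return Object of class \code{feasibility_window}: the grids, two
#'   \code{length(pH) x length(acetate)} Gibbs-energy matrices (kJ/mol), the
#'   boolean \code{window} matrix, and a \code{boundaries} data.frame (pH,
#'   fermentation_eq_acetate, methanogenesis_eq_acetate).
#' @export
feasibility_window <- function(fermentation, methanogenesis,
                               pH_grid, acetate_grid,
                               conditions_base = conditions(),
                               table = formation_energy_table()) {
  if (any(diff(pH_grid) <= 0) || any(diff(acetate_grid) <= 0))
    stop("grids must be strictly increasing", call. = FALSE)
  eval_grid <- function(rxn) {
    m <- matrix(NA_real_, length(pH_grid), length(acetate_grid),
                dimnames = list(format(pH_grid), format(acetate_grid)))
    for (i in seq_along(pH_grid)) {
      cond <- conditions_base
      cond$pH <- pH_grid[i]
      for (j in seq_along(acetate_grid))
        m[i, j] <- delta_g(rxn, .with_acetate(cond, acetate_grid[j]), table)
    }
    m
  }
  ferm <- eval_grid(fermentation)
  meth <- eval_grid(methanogenesis)
  span <- range(acetate_grid)
  eq <- function(rxn, pH) {
    cond <- conditions_base
    cond$pH <- pH
    tryCatch(equilibrium_acetate(rxn, cond, table, bounds = span),
             error = function(e) NA_real_)
  }
  boundaries <- data.frame(
    pH = pH_grid,
    fermentation_eq_acetate = vapply(pH_grid, function(p) eq(fermentation, p), 1),
    methanogenesis_eq_acetate = vapply(pH_grid, function(p) eq(methanogenesis, p), 1))
  structure(list(pH_grid = pH_grid, acetate_grid = acetate_grid,
                 fermentation_dg = ferm, methanogenesis_dg = meth,
                 window = ferm < 0 & meth < 0,
                 boundaries = boundaries,
                 reactions = c(fermentation$name, methanogenesis$name)),
            class = "feasibility_window")
}

#' @export
print.feasibility_window <- function(x, ...) {
  cat(sprintf("<feasibility_window> %s & %s\n  pH %g..%g (%d) x acetate %g..%g M (%d); %d / %d grid points feasible\n",
              x$reactions[1], x$reactions[2],
              min(x$pH_grid), max(x$pH_grid), length(x$pH_grid),
              min(x$acetate_grid), max(x$acetate_grid), length(x$acetate_grid),
              sum(x$window), length(x$window)))
  invisible(x)
}

#' Plot a feasibility window
#'
#' Shades the region where both reactions are exergonic and overlays the two
#' equilibrium-acetate boundary curves on a log acetate axis.
#'
#' @param x A \code{feasibility_window}.
#' @param ... Passed to [graphics::image()].
#' @export
plot.feasibility_window <- function(x, ...) {
  graphics::image(x$pH_grid, log10(x$acetate_grid), x$window * 1,
                  col = c("white", "lightblue"),
                  xlab = "pH", ylab = "log10 acetate (M)",
                  main = "Thermodynamic window of opportunity", ...)
  graphics::lines(x$boundaries$pH, log10(x$boundaries$fermentation_eq_acetate),
                  col = "darkgreen", lwd = 2)
  graphics::lines(x$boundaries$pH, log10(x$boundaries$methanogenesis_eq_acetate),
                  col = "firebrick", lwd = 2)
  graphics::legend("bottomright", lwd = 2, col = c("darkgreen", "firebrick"),
                   legend = c("fermentation dG = 0", "methanogenesis dG = 0"),
                   bty = "n", cex = 0.8)
  invisible(x)
}

#' Classify a well by the signs of both reaction energies
#'
#' Evaluates the fermentation and methanogenesis Gibbs energies at the
#' well's measured pH and acetate concentration (strict \code{< 0} for
#' feasibility, so a well sitting exactly on a \eqn{\Delta G = 0} boundary
#' is not feasible for that reaction).
#'
#' @param pH Measured pH.
#' @param acetate Measured acetate concentration, mol/L (> 0).
#' @param fermentation,methanogenesis [reaction()] objects.
#' @param conditions_base Base [conditions()] supplying T and the other
#'   activities.
#' @param table Formation-energy table.
#' @return One of \code{"both_feasible"}, \code{"fermentation_only"},
#'   \code{"methanogenesis_only"}, \code{"neither"}, with the two Gibbs
#'   energies attached as attribute \code{"dg"}.
#' @export
assess_well <- function(pH, acetate, fermentation, methanogenesis,
                        conditions_base = conditions(),
                        table = formation_energy_table()) {
  if (!is.finite(acetate) || acetate <= 0)
    stop("acetate concentration must be > 0", call. = FALSE)
  cond <- conditions_base
  cond$pH <- pH
  cond <- .with_acetate(cond, acetate)
  dgf <- delta_g(fermentation, cond, table)
  dgm <- delta_g(methanogenesis, cond, table)
  cls <- if (dgf < 0 && dgm < 0) "both_feasible"
         else if (dgf < 0) "fermentation_only"
         else if (dgm < 0) "methanogenesis_only"
         else "neither"
  structure(cls, dg = c(fermentation = dgf, methanogenesis = dgm))
}
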