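rx <- default_reactions()
fet <- formation_energy_table()

test_that("bundled reactions are elementally and charge balanced", {
  for (r in rx) expect_silent(invisible(
    delta_g(r, conditions(pH = 0, concentrations = c(acetate = 1, `HCO3-` = 1),
                          partial_pressures = c(CH4 = 1, H2 = 1)))))
  bad <- reaction("broken", c(CH4 = -1, CO2 = 1),
                  c(CH4 = "gas", CO2 = "gas"))
  expect_error(delta_g(bad, conditions()), "element H")
  unknown <- reaction("mystery", c(xenon = -1, CH4 = 1),
                      c(xenon = "gas", CH4 = "gas"))
  expect_error(delta_g(unknown, conditions()), "xenon")
})

test_that("at unit activities delta G equals the standard-state sum", {
  unit <- conditions(pH = 0, concentrations = c(acetate = 1, `HCO3-` = 1),
                     partial_pressures = c(CH4 = 1, H2 = 1))
  for (r in rx) {
    idx <- match(names(r$stoichiometry), fet$species)
    dg0 <- sum(r$stoichiometry * fet$dGf0[idx])
    expect_equal(delta_g(r, unit), dg0, tolerance = 1e-12, label = r$name)
  }
})

test_that("acetoclastic methanogenesis matches an independent hand summation", {
  cond <- conditions(pH = 7, concentrations = c(acetate = 1, `HCO3-` = 1),
                     partial_pressures = c(CH4 = 1, H2 = 1))
  r <- rx$acetoclastic_methanogenesis
  expect_equal(delta_g(r, cond), oracle_delta_g(r, cond), tolerance = 1e-12)
  # pH does not enter this reaction; the value is the standard-state -31 kJ/mol
  expect_equal(delta_g(r, cond), -50.75 - 586.85 - (-369.41) - (-237.18),
               tolerance = 1e-9)
  # and the oracle agrees across random in-situ conditions and temperatures
  set.seed(61)
  for (i in 1:20) {
    cond <- conditions(temperature = runif(1, 280, 370), pH = runif(1, 3, 10),
                       concentrations = c(acetate = 10^runif(1, -8, 0),
                                          `HCO3-` = 10^runif(1, -4, 0)),
                       partial_pressures = c(CH4 = 10^runif(1, -3, 1),
                                             H2 = 10^runif(1, -6, 0)))
    r2 <- rx[[sample(length(rx), 1)]]
    expect_equal(delta_g(r2, cond), oracle_delta_g(r2, cond),
                 tolerance = 1e-10)
  }
})

test_that("acetate dependence has the closed-form slope nu RT ln 10", {
  cond <- conditions()
  RT <- 8.314e-3 * cond$temperature
  for (r in list(rx$alkane_fermentation_h2, rx$alkane_fermentation_acetate,
                 rx$acetoclastic_methanogenesis)) {
    nu <- r$stoichiometry[["acetate"]]
    g1 <- delta_g(r, cond)
    cond10 <- cond
    cond10$concentrations["acetate"] <- cond$concentrations["acetate"] * 10
    expect_equal(delta_g(r, cond10) - g1, nu * RT * log(10),
                 tolerance = 1e-9, label = r$name)
  }
  # finite-difference derivative in ln[acetate] equals nu RT
  r <- rx$alkane_fermentation_acetate
  nu <- r$stoichiometry[["acetate"]]
  h <- 1e-6
  a0 <- cond$concentrations[["acetate"]]
  cp <- cond; cp$concentrations["acetate"] <- a0 * exp(h)
  cm <- cond; cm$concentrations["acetate"] <- a0 * exp(-h)
  fd <- (delta_g(r, cp) - delta_g(r, cm)) / (2 * h)
  expect_equal(fd, nu * RT, tolerance = 1e-6)
})

test_that("Hess's law holds for rational combinations of bundled reactions", {
  cond <- conditions()
  set.seed(71)
  for (i in 1:25) {
    pick <- sample(length(rx), 2)
    a <- sample(c(-6:-1, 1:6), 1) / sample(1:4, 1)
    b <- sample(c(-6:-1, 1:6), 1) / sample(1:4, 1)
    net <- combine_reactions(rx[[pick[1]]], rx[[pick[2]]], a, b)
    if (length(net$stoichiometry) == 0L) next
    expect_lt(abs(delta_g(net, cond) -
                    (a * delta_g(rx[[pick[1]]], cond) +
                     b * delta_g(rx[[pick[2]]], cond))), 1e-9)
  }
})

test_that("equilibrium acetate is a true root and matches the closed form", {
  for (r in list(rx$alkane_fermentation_acetate,
                 rx$acetoclastic_methanogenesis)) {
    cond <- conditions()
    a_eq <- equilibrium_acetate(r, cond)
    expect_lt(abs(delta_g(r, .cond_with_acetate(cond, a_eq))), 1e-6)
    expect_equal(a_eq, oracle_eq_acetate(r, cond), tolerance = 1e-9)
  }
  no_ac <- reaction("hydrogenotrophic_methanogenesis",
                    c(CO2 = -1, H2 = -4, CH4 = 1, water = 2),
                    c(CO2 = "gas", H2 = "gas", CH4 = "gas", water = "water"))
  expect_error(equilibrium_acetate(no_ac, conditions()),
               "does not involve acetate")
  expect_error(equilibrium_acetate(rx$homoacetogenesis, conditions(),
                                   bounds = c(1e-3, 1e-2)), "no sign change")
})

test_that("fermentation equilibrium acetate falls as pH falls", {
  r <- rx$alkane_fermentation_acetate   # H+ is a product
  eq <- vapply(c(5, 6, 7, 8), function(p)
    equilibrium_acetate(r, conditions(pH = p)), 1)
  expect_true(all(diff(eq) > 0))
})

test_that("the feasibility window equals brute-force grid classification", {
  pH_grid <- seq(4, 9, length.out = 8)
  ac_grid <- 10^seq(-8, 0, length.out = 9)
  fw <- feasibility_window(rx$alkane_fermentation_acetate,
                           rx$acetoclastic_methanogenesis,
                           pH_grid, ac_grid)
  for (i in seq_along(pH_grid)) for (j in seq_along(ac_grid)) {
    cond <- conditions(pH = pH_grid[i])
    cond$concentrations["acetate"] <- ac_grid[j]
    gf <- oracle_delta_g(rx$alkane_fermentation_acetate, cond)
    gm <- oracle_delta_g(rx$acetoclastic_methanogenesis, cond)
    expect_equal(fw$window[i, j], gf < 0 && gm < 0)
    expect_equal(fw$fermentation_dg[i, j], gf, tolerance = 1e-10)
  }
  expect_error(feasibility_window(rx$alkane_fermentation_acetate,
                                  rx$acetoclastic_methanogenesis,
                                  c(5, 5), ac_grid), "strictly increasing")
})

test_that("window membership is the interval between the two equilibria", {
  ac_grid <- 10^seq(-10, 0, length.out = 40)
  fw <- feasibility_window(rx$alkane_fermentation_acetate,
                           rx$acetoclastic_methanogenesis,
                           c(6, 7, 8), ac_grid)
  for (i in 1:3) {
    lo <- fw$boundaries$methanogenesis_eq_acetate[i]
    hi <- fw$boundaries$fermentation_eq_acetate[i]
    inside <- ac_grid > lo & ac_grid < hi
    expect_equal(unname(fw$window[i, ]), inside)
  }
  # increasing acetate at fixed pH never turns fermentation exergonic again
  for (i in 1:3) {
    exergonic <- fw$fermentation_dg[i, ] < 0
    expect_true(all(diff(exergonic) <= 0))
  }
})

test_that("well assessment agrees with the window and is strict at the boundary", {
  ferm <- rx$alkane_fermentation_acetate
  meth <- rx$acetoclastic_methanogenesis
  cls <- assess_well(7, 1e-4, ferm, meth)
  expect_equal(as.character(cls), "both_feasible")
  expect_true(all(attr(cls, "dg") < 0))
  expect_error(assess_well(7, -1, ferm, meth), "acetate")

  # a synthetic well placed on the fermentation dG = 0 boundary
  a_eq <- equilibrium_acetate(ferm, conditions(pH = 7))
  at_boundary <- assess_well(7, a_eq, ferm, meth)
  expect_lt(abs(attr(at_boundary, "dg")[["fermentation"]]), 1e-6)
  just_above <- assess_well(7, a_eq * (1 + 1e-5), ferm, meth)
  expect_equal(as.character(just_above), "methanogenesis_only")

  # interior wells agree with the nearest grid point
  fw <- feasibility_window(ferm, meth, seq(5, 8, 1), 10^seq(-7, -1, 1))
  set.seed(31)
  for (k in 1:10) {
    i <- sample(length(fw$pH_grid), 1)
    j <- sample(length(fw$acetate_grid), 1)
    cls <- assess_well(fw$pH_grid[i], fw$acetate_grid[j], ferm, meth)
    expect_equal(as.character(cls) == "both_feasible", fw$window[i, j])
  }
})
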