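RGAS <- 8.314e-3

test_that("standard Gibbs energy sums formation energies over the stoichiometry", {
  constants <- formation_energies()

  # water autoionization must be consistent with Kw = 1e-14 via -RT ln K
  w <- reaction_water_dissociation(constants)
  oracle <- -RGAS * 298.15 * log(1e-14)  # 79.91 kJ/mol
  expect_equal(delta_g_standard(w, constants), oracle, tolerance = 5e-4)

  # empty stoichiometry is the identity
  empty <- chem_reaction(stats::setNames(numeric(), character()))
  expect_identical(delta_g_standard(empty), 0)

  # missing constant names the species
  sub <- constants[constants$species != "Fe3+", ]
  rx <- reaction_nap_iron_oxidation(constants)
  expect_error(delta_g_standard(rx, sub), "Fe3\\+")

  # unbalanced reactions are rejected at construction
  expect_error(chem_reaction(c("Fe2+" = -1, "Fe3+" = 2), n_electrons = 1),
               "charge")
  expect_error(chem_reaction(c("NO3-" = -1, "NO2-" = 1), n_electrons = 1),
               "balanced")
})

test_that("pH re-referencing adds RT ln(10) pH_ref per proton consumed", {
  rx <- reaction_nap_iron_oxidation()

  # 1-e couple consuming 1 H+: dG0' = dG0 + RT ln(10^7)
  expect_equal(adjust_to_biological_standard(-6.1, rx, 298.15),
               -6.1 + RGAS * 298.15 * log(10) * 7, tolerance = 1e-12)
  expect_equal(adjust_to_biological_standard(-6.1, rx, 298.15), 33.86,
               tolerance = 1e-3)
  expect_equal(adjust_to_biological_standard(-6.1, rx, 283.15), 31.83,
               tolerance = 1e-3)

  # no protons: plain per-electron normalization
  no_h <- chem_reaction(c("Fe2+" = -2, "Fe3+" = 2), n_electrons = 2,
                        check = FALSE)
  expect_equal(adjust_to_biological_standard(-10, no_h), -5)

  # n_electrons = 0 cannot be normalized
  w <- reaction_water_dissociation()
  expect_error(adjust_to_biological_standard(-10, w), "n_electrons")
})

test_that("per-e-mol energies are invariant under stoichiometric scaling", {
  constants <- formation_energies()
  rx1 <- reaction_nap_iron_oxidation(constants)
  base <- delta_g_standard_biological(rx1, constants)
  for (k in c(2, 5, 10)) {
    rxk <- chem_reaction(rx1$stoichiometry * k, n_electrons = k,
                         constants = constants)
    expect_equal(delta_g_standard_biological(rxk, constants), base,
                 tolerance = 1e-12)
  }
})

test_that("whole-reaction Gibbs energies are additive (Hess's law)", {
  constants <- formation_energies()
  pool <- list(reaction_nap_iron_oxidation(constants)$stoichiometry,
               reaction_ndfo_catabolic(constants)$stoichiometry,
               reaction_water_dissociation(constants)$stoichiometry)
  dg <- function(s) delta_g_standard(chem_reaction(s, check = FALSE))
  set.seed(42)
  for (i in 1:3) {
    k <- sample(1:4, 3, replace = TRUE)
    combined <- Reduce(function(a, b) {
      all_sp <- union(names(a), names(b))
      av <- stats::setNames(rep(0, length(all_sp)), all_sp)
      av[names(a)] <- av[names(a)] + a
      av[names(b)] <- av[names(b)] + b
      av
    }, Map(function(s, kk) s * kk, pool, k))
    expect_equal(dg(combined), sum(mapply(function(s, kk) dg(s) * kk,
                                          pool, k)),
                 tolerance = 1e-9)
  }
})

test_that("in-situ correction reproduces dG' = dG0' + RT lnQ per e-mol", {
  rx <- reaction_nap_iron_oxidation()

  # Q = 1 leaves the biological standard value unchanged
  cond1 <- thermo_conditions(283.15, 7,
                             activities = c("Fe2+" = 1, "Fe3+" = 1,
                                            "NO3-" = 1, "NO2-" = 1))
  r1 <- delta_g_insitu(35.2, rx, cond1)
  expect_equal(r1$lnQ, 0)
  expect_equal(r1$dG_prime, 35.2)

  # detection-limit nitrite/nitrate with the conservative 1e-16 ratio
  cond2 <- thermo_conditions(283.15, 7,
                             activities = c("Fe2+" = 1e-4,
                                            "Fe3+" = 1e-4 * 1e-16),
                             censored = c("NO3-" = 1e-6, "NO2-" = 0.2e-6))
  r2 <- delta_g_insitu(35.2, rx, cond2)
  oracle <- 35.2 + RGAS * 283.15 * (log(1e-16) + 0.5 * log(0.2))
  expect_equal(r2$dG_prime, oracle, tolerance = 1e-9)
  expect_equal(r2$dG_prime, -53.4, tolerance = 0.05)

  # missing aqueous activity is an explicit error, never a silent 1
  cond3 <- thermo_conditions(283.15, 7,
                             activities = c("Fe2+" = 1e-4, "Fe3+" = 1e-18,
                                            "NO3-" = 1e-6))
  expect_error(delta_g_insitu(35.2, rx, cond3), "NO2-")

  # nonpositive activities rejected at condition construction
  expect_error(thermo_conditions(283.15, 7, activities = c("Fe2+" = 0)),
               "positive")
})

test_that("dG' is monotone in product and reactant activities", {
  rx <- reaction_nap_iron_oxidation()
  base <- c("Fe2+" = 1e-4, "Fe3+" = 1e-18, "NO3-" = 1e-6, "NO2-" = 1e-7)
  dg <- function(acts) {
    delta_g_insitu(35.2, rx, thermo_conditions(283.15, 7, acts))$dG_prime
  }
  for (sp in names(base)) {
    up <- base
    up[sp] <- up[sp] * 10
    if (rx$stoichiometry[sp] > 0) {
      expect_gt(dg(up), dg(base))  # more product, less favorable
    } else {
      expect_lt(dg(up), dg(base))  # more substrate, more favorable
    }
  }
})

test_that("ferric activity follows the solubility equilibrium in both conventions", {
  # shortcut convention reproduces Ksp / 10^(-3 pH)
  expect_equal(ferric_activity(1e-39, 7.1, "paper"), 2e-18,
               tolerance = 0.01)
  # standard hydroxide via Kw
  expect_equal(ferric_activity(1e-39, 7.1, "kw"), 5.0e-19,
               tolerance = 0.01)
  # algebraic identity at Ksp = 1
  expect_equal(ferric_activity(1, 5, "paper"), 10^(3 * 5))

  # slope of log10 activity vs pH is exactly +3
  ph <- seq(4, 9, by = 0.5)
  la <- log10(vapply(ph, function(p) ferric_activity(1e-39, p, "paper"),
                     numeric(1)))
  expect_equal(diff(la) / diff(ph), rep(3, length(ph) - 1),
               tolerance = 1e-9)
})

test_that("proton and ATP yields follow the -15 / -45 kJ thresholds", {
  y <- proton_atp_yield(c(-66, 0, -53.4, -44, 10))
  expect_identical(y$protons, c(4L, 0L, 3L, 2L, 0L))
  expect_identical(y$atp_feasible, c(TRUE, FALSE, TRUE, FALSE, FALSE))
  expect_error(energy_thresholds(pmf_per_proton = 15), "negative")
})

test_that("feasibility grid is monotone and its contours sit at the thresholds", {
  rx <- reaction_nap_iron_oxidation()
  fg <- feasibility_grid(rx, 35.2, 283.15, pH = c(6, 7),
                         x_range = c(-25, -5), y_range = c(-2, 2), n = 21)

  # grid value at Q = 1 (x = y = 0) equals dG0' at the reference pH
  fg0 <- feasibility_grid(rx, 35.2, 283.15, pH = 7, x_range = c(0, 1),
                          y_range = c(0, 1), n = 2)
  expect_equal(fg0$grid$dG[fg0$grid$x == 0 & fg0$grid$y == 0], 35.2)

  # strictly increasing along each axis
  for (ph in c(6, 7)) {
    sl <- fg$grid[fg$grid$pH == ph & fg$grid$y == fg$grid$y[1], ]
    expect_true(all(diff(sl$dG[order(sl$x)]) > 0))
    sl <- fg$grid[fg$grid$pH == ph & fg$grid$x == fg$grid$x[1], ]
    expect_true(all(diff(sl$dG[order(sl$y)]) > 0))
  }

  # closed-form contour: re-evaluating dG' on the contour returns the
  # threshold; at y = log10(0.2) the pmf line sits at x = -8.91
  rt10 <- RGAS * 283.15 * log(10)
  y0 <- log10(0.2)
  fgc <- feasibility_grid(rx, 35.2, 283.15, pH = 7,
                          x_range = c(-25, -5), y_range = c(y0, 2), n = 21)
  cc <- fgc$contours[fgc$contours$threshold == -15 &
                       fgc$contours$pH == 7, ]
  expect_equal(35.2 + rt10 * (cc$x + 0.5 * cc$y),
               rep(-15, nrow(cc)), tolerance = 1e-9)
  expect_equal(cc$x[cc$y == y0], (-15 - 35.2) / rt10 - 0.5 * y0,
               tolerance = 1e-9)
  expect_equal(cc$x[cc$y == y0], -8.91, tolerance = 1e-3)

  # lower intracellular pH shifts the same contour toward less extreme
  # ratios (proton-consuming couple is more favorable at pH 6)
  c6 <- fg$contours[fg$contours$threshold == -15 & fg$contours$pH == 6, ]
  c7 <- fg$contours[fg$contours$threshold == -15 & fg$contours$pH == 7, ]
  expect_true(all(c6$x > c7$x))

  expect_error(feasibility_grid(rx, 35.2, 283.15, pH = numeric()), "pH")
  expect_error(feasibility_grid(rx, 35.2, 283.15, n = 1), "2 points")
})

test_that("reactor conditions make nap-based iron oxidation favorable", {
  constants <- formation_energies()
  rx <- reaction_nap_iron_oxidation(constants)
  dG0p <- delta_g_standard_biological(rx, constants)
  fe3 <- ferric_activity(1e-39, 7.1, "paper")
  for (fe2 in c(178e-6, 236e-6)) {
    cond <- thermo_conditions(283.15, 7.1,
                              activities = c("Fe2+" = fe2, "Fe3+" = fe3),
                              censored = c("NO3-" = 1e-6,
                                           "NO2-" = 0.2e-6))
    g <- delta_g_insitu(dG0p, rx, cond)
    expect_lt(g$dG_prime, 0)
    expect_gte(g$dG_prime, -80)
    expect_lte(g$dG_prime, -40)
  }
})
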