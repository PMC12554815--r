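test_that("gas standard concentration reproduces P/(RT)", {
  cond <- venus_conditions()
  expect_equal(signif(cond$gas_standard_c, 3), 0.0409)
  # independent closed form: 101325 Pa / (8.314462618 * 298.15) / 1000
  expect_equal(cond$gas_standard_c, 101325 / (8.314462618 * 298.15) / 1000,
               tolerance = 1e-12)
  # scales inversely with T
  expect_equal(venus_conditions(temperature = 2 * 298.15)$gas_standard_c,
               cond$gas_standard_c / 2, tolerance = 1e-12)
})

test_that("activity corrections follow the species' phase class", {
  cond <- venus_conditions()
  RT <- 1.987204e-3 * 298.15
  # solute on its standard state: zero
  expect_identical(activity_correction(species_record("x", 0), cond), 0)
  # gas at 1 atm moved onto the 1 M solute standard
  g <- species_record("co2", 0, phase_class = "gas-referenced")
  expect_equal(activity_correction(g, cond), RT * log(1 / 0.040874),
               tolerance = 1e-4)
  expect_equal(activity_correction(g, cond), 1.894, tolerance = 1e-3)
  # water on the droplet activity
  w <- species_record("h2o", 0, phase_class = "fixed-activity")
  expect_equal(activity_correction(w, cond), RT * log(0.000533),
               tolerance = 1e-12)
  expect_equal(activity_correction(w, cond), -4.466, tolerance = 1e-3)
  # concentrated acid on the 1 M solute standard
  acid <- species_record("h2so4", 0)
  expect_equal(activity_correction(acid, cond), RT * log(16.3),
               tolerance = 1e-12)
  # fixed-activity species with no declared activity is a config error
  orphan <- species_record("mystery", 0, phase_class = "fixed-activity")
  expect_error(activity_correction(orphan, cond), "no activity")
})

test_that("reaction energies sum chemical potentials and negate on reversal", {
  lib <- species_library(list(
    species_record("a", -10), species_record("b", -20),
    species_record("h2o", 3.3, phase_class = "fixed-activity")))
  cond <- venus_conditions()
  rxn <- reaction("condensation", c(a = -2, b = 1, h2o = 1))
  # standard state: raw free-energy sum
  cond1 <- unit_water_conditions()
  expect_equal(reaction_delta_g(rxn, lib, cond1), -20 + 3.3 + 20)
  # Venus water activity shifts by nu_w RT ln a_w
  expect_equal(reaction_delta_g(rxn, lib, cond) -
                 reaction_delta_g(rxn, lib, cond1),
               1.987204e-3 * 298.15 * log(0.000533), tolerance = 1e-12)
  expect_equal(reaction_delta_g(rxn, lib, cond) -
                 reaction_delta_g(rxn, lib, cond1), -4.466, tolerance = 1e-3)
  # exact antisymmetry
  expect_identical(reaction_delta_g(reverse_reaction(rxn), lib, cond),
                   -reaction_delta_g(rxn, lib, cond))
  # lookup error names the missing species
  bad <- reaction("bad", c(a = -1, ghost = 1))
  expect_error(reaction_delta_g(bad, lib, cond), "ghost")
})

test_that("charge and element balance are enforced", {
  lib <- species_library(list(
    species_record("cat", 0, charge = 1L),
    species_record("neu", 0),
    species_record("an", 0, charge = -1L),
    species_record("h2o", 0, formula = c(H = 2, O = 1)),
    species_record("oh", 0, formula = c(H = 1, O = 1))))
  cond <- unit_water_conditions()
  expect_error(
    reaction_delta_g(reaction("r", c(cat = -1, neu = 1)), lib, cond),
    "charge")
  expect_no_error(
    reaction_delta_g(reaction("r", c(cat = -1, an = -1, neu = 2)), lib, cond))
  expect_error(
    reaction_delta_g(reaction("r", c(h2o = -1, oh = 1)), lib, cond),
    "imbalance")
})

test_that("Hess additivity matches a brute-force chemical-potential oracle", {
  set.seed(421)
  for (rep in 1:5) {
    net <- random_network()
    cond <- venus_conditions(
      temperature = runif(1, 250, 400),
      activities = c(h2o = runif(1, 1e-4, 1)),
      concentrations = c(sp1 = runif(1, 0.1, 20)))
    weights <- sample(-3:3, length(net$reactions), replace = TRUE)
    # summed reaction via stoichiometry algebra
    total <- numeric(0)
    for (i in seq_along(net$reactions)) {
      nu <- weights[i] * net$reactions[[i]]$stoichiometry
      for (id in names(nu)) {
        total[id] <- if (id %in% names(total)) total[id] + nu[[id]] else nu[[id]]
      }
    }
    total <- total[abs(total) > 1e-12]
    if (!any(total < 0) || !any(total > 0)) next
    lhs <- reaction_delta_g(reaction("sum", total), net$lib, cond)
    # oracle: independent per-species mu summation
    RT <- 1.987204e-3 * cond$temperature
    mu <- function(id) {
      g <- net$lib$records[[id]]$free_energy
      if (id %in% names(cond$concentrations)) {
        g + RT * log(cond$concentrations[[id]])
      } else g
    }
    oracle <- sum(vapply(names(total), function(id) total[[id]] * mu(id),
                         numeric(1)))
    expect_equal(lhs, oracle, tolerance = 1e-10)
    # and equals the weighted sum of per-reaction energies
    parts <- vapply(net$reactions, function(r)
      reaction_delta_g(r, net$lib, cond), numeric(1))
    expect_equal(lhs, sum(weights * parts), tolerance = 1e-8)
  }
})

test_that("water-activity scans are linear in ln(a_w) with slope nu_w RT", {
  lib <- species_library(list(
    species_record("a", -30), species_record("b", -25),
    species_record("h2o", 3.5, phase_class = "fixed-activity")))
  cond <- venus_conditions()
  aw <- 10^seq(-4, 0, length.out = 9)
  for (nu_w in c(-2, 1, 2)) {
    rxn <- reaction("r", c(a = -1, b = 1, h2o = nu_w))
    scan <- water_activity_scan(rxn, lib, cond, activities = aw)
    fit <- stats::lm(delta_g ~ log(a_w), data = scan)
    expect_equal(unname(coef(fit)[2]), nu_w * 1.987204e-3 * 298.15,
                 tolerance = 1e-9)
    expect_equal(unname(max(abs(residuals(fit)))), 0, tolerance = 1e-9)
    # monotone in a_w when nu_w != 0; water-producing reactions become more
    # favorable as the droplet dries
    expect_true(all(diff(scan$delta_g) * sign(nu_w) > 0))
  }
  # nu_w = 0: constant
  rxn0 <- reaction("r0", c(a = -1, b = 1))
  scan0 <- water_activity_scan(rxn0, lib, cond, activities = aw)
  expect_equal(diff(range(scan0$delta_g)), 0)
  expect_error(water_activity_scan(rxn0, lib, cond, activities = numeric(0)),
               "nonempty")
})

test_that("the bundled reaction set reproduces the corrected energy table", {
  lib <- read_library(fixture_path("synthetic_venus_library.json"))
  rxns <- read_reaction_set(fixture_path("synthetic_reaction_set.json"))
  tab <- reaction_table(rxns, lib, venus_conditions())
  expect_equal(nrow(tab), 12L)
  expect_equal(tab$delta_g, tab$delta_g_raw + tab$correction,
               tolerance = 1e-10)
  # monomer-forming and polymer-forming routes are exergonic
  expect_true(all(tab$delta_g[grepl("r[2-7]", tab$label)] < 0))
  # hydration of metaphosphoric acid turns endergonic at Venus water activity
  r9 <- rxns[[which(grepl("r9", tab$label))]]
  expect_gt(tab$delta_g[grepl("r9", tab$label)], 0)
  expect_lt(reaction_delta_g(r9, lib, unit_water_conditions()), 0)
  # tetramer hydrolysis stays spontaneous
  expect_lt(tab$delta_g[grepl("r10", tab$label)], 0)
})
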