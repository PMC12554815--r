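test_that("insertion energies invert the generator and relax toward g_inf", {
  cond <- venus_conditions()
  # strain-free, noiseless: every step is exactly the asymptote
  s0 <- generate_series(generator_spec(sigma = 0, strain = 0, max_n = 6),
                        cond)
  for (n in 1:5) expect_equal(insertion_delta_g(s0, n, cond), -1,
                              tolerance = 1e-10)
  # strained: the ring-closure step is penalized above the asymptote,
  # later steps approach it from below
  s1 <- generate_series(generator_spec(sigma = 0, strain = 6, max_n = 8),
                        cond)
  dg <- vapply(1:7, function(n) insertion_delta_g(s1, n, cond), numeric(1))
  expect_gt(dg[1], -1)            # small-ring closure penalized
  expect_gt(dg[1], dg[7])         # small n less favorable than large n
  expect_true(all(diff(dg[-1]) > 0))  # monotone relaxation for n >= 2
  expect_equal(dg[7], -1 + 6 * (8^-1 - 7^-1), tolerance = 1e-10)
  expect_error(insertion_delta_g(s1, 99, cond), "not in series")
})

test_that("insertion bookkeeping equals the explicit reaction route", {
  cond <- venus_conditions()
  s <- generate_series(generator_spec(sigma = 0.05, strain = 4, max_n = 6,
                                      seed = 7), cond)
  lib <- species_library(c(list(s$monomer, s$water), unname(s$cycles)))
  for (n in 2:5) {
    rxn <- insertion_reaction(s, n)
    expect_equal(insertion_delta_g(s, n, cond),
                 reaction_delta_g(rxn, lib, cond), tolerance = 1e-10)
  }
})

test_that("insertion steps telescope to the direct N-merization energy", {
  cond <- unit_water_conditions()
  s <- generate_series(generator_spec(sigma = 0.02, strain = 5, max_n = 6,
                                      seed = 11), cond)
  lib <- species_library(c(list(s$monomer, s$water), unname(s$cycles)))
  N <- 6
  stepsum <- sum(vapply(1:(N - 1), function(n)
    insertion_delta_g(s, n, cond), numeric(1)))
  direct <- reaction(
    "direct", stats::setNames(c(-N, 1, N - 1),
                              c(s$monomer$identifier, paste0("cyc_", N),
                                s$water$identifier)))
  expect_equal(stepsum, reaction_delta_g(direct, lib, cond),
               tolerance = 1e-10)
})

test_that("per-unit energies and proxy selection follow the strain model", {
  # single cycle: one entry, G/n
  one <- oligomer_series(species_record("m", -10),
                         species_record("h2o", 0),
                         list("4" = species_record("cyc_4", -100)))
  pu <- per_unit_free_energy(one)
  expect_equal(pu$g_per_unit, -25)
  expect_equal(select_cyclic_proxy(one), 4L)
  # strain-free: constant per-unit value
  s0 <- generate_series(generator_spec(sigma = 0, strain = 0))
  expect_equal(diff(range(per_unit_free_energy(s0)$g_per_unit)), 0,
               tolerance = 1e-10)
  # strained: strictly decreasing, so the largest cycle is the proxy
  s1 <- generate_series(generator_spec(sigma = 0, strain = 6, max_n = 7))
  expect_true(all(diff(per_unit_free_energy(s1)$g_per_unit) < 0))
  expect_equal(select_cyclic_proxy(s1), 7L)
  # ties break toward the smallest n
  tie <- oligomer_series(species_record("m", -10), species_record("h2o", 0),
                         list("2" = species_record("c2", -20),
                              "4" = species_record("c4", -40)))
  expect_equal(select_cyclic_proxy(tie), 2L)
})

test_that("ring strain estimates recover the generator's strain law", {
  s <- generate_series(generator_spec(sigma = 0, strain = 6, max_n = 8))
  # explicit reference: s/n^2 per unit, so n = 2 carries 1.5 kcal/mol
  rs <- ring_strain(s, n = 2, reference = attr(s, "truth")$u_inf)
  expect_equal(rs$strain_per_unit, 1.5, tolerance = 1e-10)
  # asymptote mode reproduces the same numbers on a clean series
  rs_all <- ring_strain(s)
  expect_equal(attr(rs_all, "reference"), attr(s, "truth")$u_inf,
               tolerance = 1e-8)
  expect_true(all(rs_all$strain_per_unit >= -1e-8))
  expect_true(all(diff(rs_all$strain_per_unit) < 0))
  # strain-free fixture: zero at all n
  s0 <- generate_series(generator_spec(sigma = 0, strain = 0))
  rs0 <- ring_strain(s0)
  expect_equal(rs0$strain_per_unit, rep(0, nrow(rs0)), tolerance = 1e-8)
  # too few sizes for asymptote mode
  one <- oligomer_series(species_record("m", -10), species_record("h2o", 0),
                         list("4" = species_record("c4", -40)))
  expect_error(ring_strain(one), ">= 3")
})

test_that("bond dissociation uses fragment-minus-parent enthalpies", {
  gl <- generate_library(generator_spec(), weakest_bde = 50)
  tab <- bond_dissociation(gl$cleavage)
  wk <- weakest_channel(gl$cleavage)
  expect_equal(wk$bde, 50, tolerance = 1e-10)
  expect_equal(wk$mode, "heterolytic")
  expect_true(all(tab$bde >= wk$bde))
  # a heterolytic channel below all homolytic ones is preferred
  expect_lt(min(tab$bde[tab$mode == "heterolytic"]),
            min(tab$bde[tab$mode == "homolytic"]))
  # null channel: fragments identical to an unsplit parent
  parent <- species_record("p", -10, enthalpy = -12)
  whole <- species_record("p_copy", -10, enthalpy = -12)
  ghost <- species_record("nil", 0, enthalpy = 0)
  cs <- cleavage_set(parent, list(list(label = "null", mode = "homolytic",
                                       fragments = list(whole, ghost))))
  expect_equal(bond_dissociation(cs)$bde, 0)
  # missing enthalpy names the record
  noH <- species_record("noH", -1)
  cs2 <- cleavage_set(parent, list(list(label = "x", mode = "homolytic",
                                        fragments = list(noH, ghost))))
  expect_error(bond_dissociation(cs2), "noH")
  # charge bookkeeping of channels
  an <- species_record("an", 0, enthalpy = 0, charge = -1L)
  expect_error(cleavage_set(parent, list(list(label = "y", mode = "homolytic",
                                              fragments = list(an, ghost)))),
               "neutral")
})

test_that("IP and EA come from charge-state energy differences in eV", {
  ev <- constants_table()$eV_kcal
  neutral <- species_record("m", -1000, phase_class = "gas-referenced")
  cation <- species_record("m_cat", -1000 + 11.2 * ev, charge = 1L,
                           phase_class = "gas-referenced")
  anion <- species_record("m_an", -1000 - 1.2 * ev, charge = -1L,
                          phase_class = "gas-referenced")
  res <- ip_ea(neutral, cation, anion)
  expect_equal(res$ip, 11.2, tolerance = 1e-10)
  expect_equal(res$ea, 1.2, tolerance = 1e-10)
  # gauge invariance under a common shift
  shift <- function(r, d) { r$free_energy <- r$free_energy + d; r }
  res2 <- ip_ea(shift(neutral, 123.4), shift(cation, 123.4),
                shift(anion, 123.4))
  expect_equal(res2$ip, res$ip)
  expect_equal(res2$ea, res$ea)
  # degenerate case and charge-pattern validation
  expect_equal(ip_ea(neutral, shift(cation, -(11.2 * ev)), anion)$ip, 0,
               tolerance = 1e-10)
  expect_error(ip_ea(neutral, anion, cation), "charge pattern")
})
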