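test_that("broadened IR spectra peak at the line positions and conserve intensity", {
  one <- data.frame(wavenumber = 845, intensity = 100)
  sp <- broaden_ir(one, width = 20)
  expect_equal(sp$axis[which.max(sp$values)], 845, tolerance = 0.5)
  # integral conservation: Gaussian lineshape is compact
  two <- data.frame(wavenumber = c(7000, 7100), intensity = c(120, 380))
  spg <- broaden_ir(two, width = 20, shape = "gaussian")
  expect_equal(spectrum_integral(spg), 500, tolerance = 1e-4)
  # Lorentzian wings need a wide grid for the same 0.1% conservation
  spl <- broaden_ir(two, width = 20, range = c(7050 - 6500, 7050 + 6500))
  expect_equal(spectrum_integral(spl), 500, tolerance = 1e-3)
  # two equal lines 16 cm-1 apart at 8 cm-1 width resolve into two maxima
  pair <- data.frame(wavenumber = c(845, 861), intensity = c(1, 1))
  spp <- broaden_ir(pair, width = 8, resolution = 0.1)
  y <- spp$values
  n_max <- sum(y[2:(length(y) - 1)] > y[1:(length(y) - 2)] &
               y[2:(length(y) - 1)] > y[3:length(y)])
  expect_equal(n_max, 2L)
  # frequency scaling moves the axis of the peak
  sps <- broaden_ir(one, width = 20, scale = 0.97)
  expect_equal(sps$axis[which.max(sps$values)], 845 * 0.97, tolerance = 0.5)
  expect_error(broaden_ir(one[0, ]), "empty")
})

test_that("spectral broadening is linear in the line list", {
  a <- data.frame(wavenumber = c(500, 700), intensity = c(10, 40))
  b <- data.frame(wavenumber = c(650, 900), intensity = c(25, 5))
  rng <- c(300, 1100)
  sa <- broaden_ir(a, range = rng)
  sb <- broaden_ir(b, range = rng)
  sab <- broaden_ir(rbind(a, b), range = rng)
  expect_equal(sab$values, sa$values + sb$values, tolerance = 1e-12)
  # same additivity for the UV-Vis convolution
  ea <- data.frame(energy_ev = 6.5, oscillator_strength = 0.2)
  eb <- data.frame(energy_ev = 7.5, oscillator_strength = 0.1)
  er <- c(4, 10)
  ua <- uvvis_spectrum(ea, energy_range = er)
  ub <- uvvis_spectrum(eb, energy_range = er)
  uab <- uvvis_spectrum(rbind(ea, eb), energy_range = er)
  expect_equal(uab$values, ua$values + ub$values, tolerance = 1e-12)
})

test_that("UV-Vis convolution converts energies to wavelength and drops dark states", {
  one <- data.frame(energy_ev = 7.75, oscillator_strength = 0.3)
  sp <- uvvis_spectrum(one)
  expect_equal(sp$axis[which.max(sp$values)], 160.0, tolerance = 0.1)
  expect_true(all(diff(sp$axis) > 0))
  dark <- data.frame(energy_ev = c(5, 6), oscillator_strength = c(0, 0),
                     multiplicity = "triplet")
  expect_equal(max(uvvis_spectrum(dark)$values), 0)
  expect_error(uvvis_spectrum(dark[0, ]), "empty")
})

test_that("window fractions integrate to one over a partition", {
  exc <- data.frame(energy_ev = c(7.0, 7.5, 8.2),
                    oscillator_strength = c(0.2, 0.35, 0.1))
  sp <- uvvis_spectrum(exc, energy_range = c(3, 12))
  expect_equal(window_fraction(sp, range(sp$axis)), 1, tolerance = 1e-9)
  cuts <- c(min(sp$axis), 150, 200, 300, max(sp$axis))
  parts <- vapply(1:4, function(i)
    window_fraction(sp, c(cuts[i], cuts[i + 1])), numeric(1))
  expect_equal(sum(parts), 1, tolerance = 0.01)
  # spectrum entirely below 220 nm has nothing beyond it
  blue <- uvvis_spectrum(data.frame(energy_ev = 7.75,
                                    oscillator_strength = 0.3),
                         energy_range = c(1239.84198 / 300, 10))
  expect_equal(window_fraction(blue, c(220, Inf)), 0, tolerance = 1e-6)
  expect_warning(frac <- window_fraction(blue, c(500, 600)), "disjoint")
  expect_equal(frac, 0)
  # a 170 nm emitter leaves essentially nothing in the 320-400 nm window
  deep <- uvvis_spectrum(data.frame(energy_ev = 1239.84198 / 170,
                                    oscillator_strength = 0.3),
                         energy_range = c(2.5, 10))
  expect_lt(window_fraction(deep, c(320, 400)), 0.01)
})

test_that("diagnostic windows flag bands clear of every reference", {
  tgt <- band_table("poly", c(845, 861, 1452, 700), c(500, 450, 400, 150))
  refs <- list(band_table("acid", c(1450, 891), c(400, 350)),
               band_table("oxide", c(1391), c(520)))
  out <- diagnostic_windows(tgt, refs, tolerance = 15)
  expect_equal(out$wavenumber, c(845, 861))
  # empty reference list: every qualifying band returned
  all_strong <- diagnostic_windows(tgt, list(), tolerance = 15)
  expect_equal(all_strong$wavenumber, c(845, 861, 1452))
  # class filter: medium admits the 700 band too
  med <- diagnostic_windows(tgt, refs, tolerance = 15, min_class = "medium")
  expect_true(700 %in% med$wavenumber)
  # boundary case: exactly tolerance away is excluded (strict inequality)
  tgt2 <- band_table("poly", 900, 500)
  ref2 <- band_table("acid", 885, 400)
  expect_equal(nrow(diagnostic_windows(tgt2, ref2, tolerance = 15)), 0L)
  expect_equal(nrow(diagnostic_windows(tgt2, ref2, tolerance = 14.999)), 1L)
  # invariant under reference ordering
  out_rev <- diagnostic_windows(tgt, rev(refs), tolerance = 15)
  expect_equal(out$wavenumber, out_rev$wavenumber)
  expect_error(diagnostic_windows(tgt[0, ], refs), "empty")
})

test_that("band tables round-trip through delimited text", {
  path <- withr::local_tempfile(fileext = ".csv")
  tb <- band_table("poly", c(845, 861, 700), c(500, 450, 120),
                   c("P-O-S", "P-O-S", "bend"))
  utils::write.csv(tb[c("molecule", "wavenumber", "intensity", "assignment")],
                   path, row.names = FALSE)
  tb2 <- read_band_table(path)
  expect_equal(tb2$wavenumber, tb$wavenumber)
  expect_equal(as.character(tb2$class), as.character(tb$class))
  expect_error(band_table("x", -1, 10), "> 0")
})

test_that("spectra serialize with a self-describing header", {
  sp <- broaden_ir(data.frame(wavenumber = 845, intensity = 10), width = 12)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_spectrum(sp, path)
  lines <- readLines(path)
  expect_true(any(grepl("lineshape: lorentzian", lines)))
  expect_true(any(grepl("width: 12", lines)))
  df <- utils::read.table(path, header = TRUE, comment.char = "#")
  expect_equal(nrow(df), length(sp$axis))
})
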