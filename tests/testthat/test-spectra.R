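test_that("find_peaks recovers Gaussian band centers within 0.5 nm", {
  s <- simulate_spectrum(data.frame(center = c(291, 354), width = 12,
                                    amplitude = c(0.6, 0.4)), seed = 1)
  pk <- find_peaks(s)
  expect_equal(nrow(pk), 2L)
  expect_lt(max(abs(pk$center_nm - c(291, 354))), 0.5)
  # off-grid center still refined to sub-grid accuracy by the parabola
  s2 <- simulate_spectrum(data.frame(center = 354.4, width = 12, amplitude = 1),
                          seed = 1)
  expect_lt(abs(find_peaks(s2)$center_nm - 354.4), 0.5)
})

test_that("monotone and flat signals yield no peaks", {
  mono <- spectrum(300:400, seq(0, 1, length.out = 101), "absorption")
  expect_identical(nrow(find_peaks(mono)), 0L)
  flat <- spectrum(300:400, rep(0.3, 101), "absorption")
  expect_identical(nrow(find_peaks(flat)), 0L)
})

test_that("a single symmetric band peaks at its center; plateaus break long", {
  s <- simulate_spectrum(data.frame(center = 400, width = 15, amplitude = 1),
                         grid = c(300, 500, 1), seed = 1)
  pk <- find_peaks(s)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$center_nm, 400, tolerance = 1e-6)
  # two-point plateau: single candidate, biased toward the longer-wavelength
  # end of the plateau (discrete tie-break), refined within the plateau
  plat <- spectrum(c(1:5) + 300, c(0, 1, 1, 0.5, 0), "absorption")
  pk_p <- find_peaks(plat)
  expect_identical(nrow(pk_p), 1L)
  expect_gte(pk_p$center_nm, 302)
  expect_lte(pk_p$center_nm, 303)
})

test_that("stokes_shift matches the wavenumber formula and is antisymmetric", {
  expect_equal(stokes_shift(291, 430), 11108, tolerance = 1 / 11108)
  expect_equal(stokes_shift(250, 445), 17528, tolerance = 1 / 17528)
  expect_identical(stokes_shift(400, 400), 0)
  for (lp in list(c(291, 430), c(263, 462), c(350, 500)))
    expect_equal(stokes_shift(lp[1], lp[2]), -stokes_shift(lp[2], lp[1]))
  expect_error(stokes_shift(-1, 430), class = "fluorsense_domain_error")
})

test_that("molar absorptivity is Beer-Lambert arithmetic with an inverse", {
  expect_equal(molar_absorptivity(0.5, 1e-5, 1), 5e4)
  expect_equal(molar_absorptivity(0, 1e-5, 1), 0)
  eps <- 1.5107e4
  A <- eps * 1e-5 * 1   # absorbance from epsilon
  expect_equal(molar_absorptivity(A, 1e-5, 1), eps, tolerance = 1e-12)
  expect_error(molar_absorptivity(0.5, 0, 1), class = "fluorsense_domain_error")
})

test_that("normalize is idempotent and preserves peak positions", {
  s <- simulate_spectrum(data.frame(center = c(291, 354), width = 12,
                                    amplitude = c(0.6, 0.4)), seed = 1)
  n1 <- normalize_spectrum(s)
  expect_equal(max(n1$signal), 1)
  n2 <- normalize_spectrum(n1)
  expect_identical(n1$signal, n2$signal)
  expect_equal(find_peaks(n1)$center_nm, find_peaks(s)$center_nm)
  zero <- spectrum(1:10 + 300, rep(0, 10), "absorption")
  expect_error(normalize_spectrum(zero), class = "fluorsense_domain_error")
})

test_that("the photophysics table reproduces tabulated Stokes shifts", {
  series <- make_table4_series()
  tab <- photophysics_table(series)
  expect_identical(tab$solvent, table4$solvent)
  expect_true(all(tab$complete))
  # shortest-wavelength absorption band is paired with the emission maximum
  expect_equal(tab$lambda_abs_used, table4$abs1, tolerance = 1e-6)
  expect_equal(tab$lambda_emi, table4$emi, tolerance = 1e-6)
  expect_equal(tab$stokes_cm1, stokes_shift(table4$abs1, table4$emi),
               tolerance = 1e-6)
  # both absorption maxima are listed per solvent
  expect_identical(tab$lambda_abs[1], "291,354")
  # epsilon from the recorded concentration: amplitude 0.6 at 1e-5 M
  expect_equal(tab$epsilon, rep(0.6 / 1e-5, 6), tolerance = 1e-3)
  # longest-band pairing is available as an option
  tab_l <- photophysics_table(series, band = "longest")
  expect_equal(tab_l$lambda_abs_used, table4$abs2, tolerance = 1e-6)
})

test_that("degenerate photophysics rows are flagged, not dropped silently", {
  coincident <- list(list(
    absorption = simulate_spectrum(data.frame(center = 400, width = 12, amplitude = 1),
                                   seed = 1, solvent = "x"),
    emission = simulate_spectrum(data.frame(center = 400, width = 12, amplitude = 1),
                                 seed = 1, kind = "emission", solvent = "x")))
  tab <- photophysics_table(coincident)
  expect_equal(tab$stokes_cm1, 0, tolerance = 1e-9)
  blue <- list(list(
    absorption = simulate_spectrum(data.frame(center = 450, width = 12, amplitude = 1),
                                   seed = 1, solvent = "x"),
    emission = simulate_spectrum(data.frame(center = 400, width = 12, amplitude = 1),
                                 seed = 1, kind = "emission", solvent = "x")))
  tab_b <- photophysics_table(blue)
  expect_lt(tab_b$stokes_cm1, 0)
  expect_identical(tab_b$flag, "emission blue of absorption")
  flatpair <- list(list(
    absorption = spectrum(300:310, rep(0, 11), "absorption", solvent = "x"),
    emission = simulate_spectrum(data.frame(center = 400, width = 12, amplitude = 1),
                                 seed = 1, kind = "emission", solvent = "x")))
  tab_f <- photophysics_table(flatpair)
  expect_false(tab_f$complete)
})

test_that("bathochromic range is max minus min across solvents", {
  tab <- photophysics_table(make_table4_series())
  expect_equal(bathochromic_range(tab, "emission"), 32, tolerance = 1e-6)
  expect_equal(bathochromic_range(tab, "absorption_longest"),
               max(table4$abs2) - min(table4$abs2), tolerance = 1e-6)
  two <- tab[1:2, ]
  two$lambda_emi <- c(440, 450)
  expect_equal(bathochromic_range(two, "emission"), 10)
  same <- tab
  same$lambda_emi <- 445
  expect_equal(bathochromic_range(same, "emission"), 0)
  expect_error(bathochromic_range(tab[1, , drop = FALSE]),
               class = "fluorsense_domain_error")
})

test_that("spectra round-trip through the CSV dialect with metadata", {
  s <- simulate_spectrum(data.frame(center = c(291, 354), width = 12,
                                    amplitude = c(0.6, 0.4)),
                         seed = 7, noise_sd = 0.005, solvent = "ACN",
                         concentration = 1e-5)
  path <- tempfile(fileext = ".csv")
  write_spectrum_csv(s, path)
  s2 <- read_spectrum_csv(path)
  expect_equal(s2$wavelength, s$wavelength)
  expect_equal(s2$signal, s$signal, tolerance = 1e-9)
  expect_identical(s2$meta$solvent, "ACN")
  expect_equal(s2$meta$concentration, 1e-5)
  expect_identical(s2$kind, "absorption")
})
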