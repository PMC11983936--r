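test_that("Stern-Volmer fits recover a planted constant exactly on clean data", {
  q <- seq(0, 3e-7, length.out = 10)
  for (ksv in c(6.52e6, 1e6, 2.3e5)) {
    t <- simulate_titration(q, "dynamic_SV", Ksv = ksv, I0 = 1000, seed = 1)
    free <- stern_volmer_fit(t)
    fixed <- stern_volmer_fit(t, fix_intercept = TRUE)
    expect_equal(free$Ksv, ksv, tolerance = 1e-6, label = sprintf("free Ksv=%g", ksv))
    expect_equal(free$intercept, 1, tolerance = 1e-6)
    expect_equal(fixed$Ksv, ksv, tolerance = 1e-10, label = sprintf("fixed Ksv=%g", ksv))
    expect_identical(fixed$intercept, 1)
  }
})

test_that("constant intensity means no quenching: Ksv = 0, intercept = 1", {
  t <- titration_series(seq(0, 1e-6, length.out = 6), rep(800, 6))
  fit <- stern_volmer_fit(t)
  expect_lt(abs(fit$Ksv), 1e-6)   # negligible against any real Ksv (~1e6 M^-1)
  expect_equal(fit$intercept, 1, tolerance = 1e-12)
  expect_false(fit$intercept_flag)
})

test_that("a noisy titration still recovers Ksv within 10%", {
  ksv <- 6.52e6
  t <- simulate_titration(seq(0, 3e-7, length.out = 10), "dynamic_SV",
                          Ksv = ksv, I0 = 1000, noise_sd = 10, seed = 42)
  fit <- stern_volmer_fit(t)
  expect_lt(abs(fit$Ksv - ksv) / ksv, 0.10)
})

test_that("Stern-Volmer preconditions are enforced", {
  t <- titration_series(c(0, 1e-7, 2e-7), c(1000, 900, 800))
  expect_error(stern_volmer_fit(t, range_mask = c(TRUE, TRUE, FALSE)),
               class = "fluorsense_domain_error")
  neg <- titration_series(c(0, 1e-7, 2e-7, 3e-7), c(1000, 900, 0.0, -5),
                          I0 = 1000)
  expect_error(stern_volmer_fit(neg), class = "fluorsense_domain_error")
  # a range mask excluding the nonlinear tail restores the linear estimate
  q <- seq(0, 2e-6, length.out = 12)
  ka <- 1e6
  t_static <- simulate_titration(q, "static_complex", Ka = ka,
                                 probe_conc = 1e-5, seed = 3)
  masked <- stern_volmer_fit(t_static, range_mask = q <= 5e-7)
  expect_equal(masked$n_points_used, sum(q <= 5e-7))
})

test_that("quenching efficiency is a scale-free percent drop", {
  expect_equal(quenching_efficiency(1000, 1000), 0)
  expect_equal(quenching_efficiency(1000, 0), 100)
  expect_equal(quenching_efficiency(1000, 500), 50)
  expect_lt(quenching_efficiency(1000, 1200), 0)  # enhancement is negative
  for (k in c(0.5, 3, 1e4))
    expect_equal(quenching_efficiency(k * 1000, k * 400),
                 quenching_efficiency(1000, 400))
})

test_that("detection limit satisfies the 3-sigma/slope identity exactly", {
  sim <- simulate_lod_calibration(5.89e8, 0.35, seed = 11)
  fit <- detection_limit(sim$calibration, sim$blanks)
  expect_equal(fit$lod * abs(fit$slope), 3 * fit$sigma_blank,
               tolerance = 1e-14)
  expect_equal(fit$sigma_blank, sd(sim$blanks))
  zero <- simulate_lod_calibration(5.89e8, 0, seed = 11)
  expect_identical(detection_limit(zero$calibration, zero$blanks)$lod, 0)
  expect_error(detection_limit(sim$calibration, sim$blanks[1:2]),
               class = "fluorsense_domain_error")
})

test_that("detection limit accepts both response conventions", {
  sim <- simulate_lod_calibration(-5.89e8, 0.35, seed = 12)  # turn-off slope
  raw <- detection_limit(sim$calibration, sim$blanks, response = "intensity")
  delta <- detection_limit(sim$calibration, sim$blanks, response = "delta_intensity")
  expect_lt(raw$slope, 0)
  expect_gt(delta$slope, 0)
  expect_equal(raw$lod, delta$lod, tolerance = 1e-12)
})

test_that("Job analysis identifies 1:1 and 1:2 stoichiometries", {
  j11 <- simulate_job_series(1e6, 2e-5, c(1, 1), 11, seed = 1)
  r11 <- job_analyze(j11)
  expect_equal(r11$x_max, 0.5, tolerance = 0.01 / 0.5)
  expect_identical(r11$ratio_label, "1:1")
  expect_gte(r11$curve_symmetry, 0.999)
  expect_false(r11$inconclusive)

  j12 <- simulate_job_series(1e10, 2e-5, c(1, 2), 11, seed = 1)
  r12 <- job_analyze(j12)
  expect_equal(r12$x_max, 1 / 3, tolerance = 0.035)
  expect_identical(r12$ratio_label, "1:2")

  # guest-poor analogue mirrors to n:1
  j21 <- simulate_job_series(1e10, 2e-5, c(2, 1), 11, seed = 1)
  expect_identical(job_analyze(j21)$ratio_label, "2:1")
})

test_that("an exact symmetric parabola peaks at one half exactly", {
  x <- seq(0.1, 0.9, by = 0.1)
  j <- job_series(x, 1 - (x - 0.5)^2)
  expect_identical(job_analyze(j)$x_max, 0.5)
})

test_that("edge maxima make the Job result inconclusive", {
  x <- seq(0.1, 0.9, by = 0.1)
  j <- job_series(x, x)  # monotone: max at the boundary
  r <- job_analyze(j)
  expect_true(r$inconclusive)
  expect_match(r$reason, "edge")
  expect_true(is.na(r$ratio_label))
})

test_that("baseline correction removes a linear drift before peak location", {
  x <- seq(0.1, 0.9, by = 0.08)
  drift <- 5 + 3 * x
  sig <- 1 - (x - 0.5)^2 + drift
  r <- job_analyze(job_series(x, sig), baseline_correction = TRUE)
  expect_equal(r$x_max, 0.5, tolerance = 0.02)
})

test_that("selectivity panel flags the strongest quencher only", {
  resp <- c(PA = 100, `2NP` = 960, `3NP` = 950, `4NP` = 970, `3NA` = 985,
            ANP = 955)
  panel <- selectivity_panel(1000, resp)
  expect_identical(panel$selective_for, "PA")
  expect_gte(panel$response[["PA"]], 0.9)
  expect_true(all(panel$response[names(resp) != "PA"] <= 0.06))
  none <- selectivity_panel(1000, c(a = 1000, b = 1000))
  expect_true(is.na(none$selective_for))
  single <- selectivity_panel(1000, c(PA = 10))
  expect_identical(single$selective_for, "PA")
  expect_error(selectivity_panel(1000, numeric(0)),
               class = "fluorsense_domain_error")
})

test_that("interference mode reports the retained response per competitor", {
  intf <- data.frame(competitor = c("2NP", "3NP"),
                     I_competitor = c(950, 940),
                     I_competitor_target = c(120, 130))
  panel <- selectivity_panel(1000, c(PA = 100), interference = intf)
  expect_true(all(panel$interference$retained_response > 0.85))
})

test_that("reversibility index interpolates between no and full recovery", {
  expect_equal(reversibility_index(1000, 200, 1000)$index, 1)
  expect_equal(reversibility_index(1000, 200, 200)$index, 0)
  expect_equal(reversibility_index(1000, 200, 600)$index, 0.5)
  over <- reversibility_index(1000, 200, 1100)
  expect_identical(over$index, 1)
  expect_gt(over$raw, 1)
  for (k in c(0.1, 7))
    expect_equal(reversibility_index(k * 1000, k * 200, k * 600)$index, 0.5)
  expect_error(reversibility_index(1000, 1000, 1000),
               class = "fluorsense_domain_error")
})

test_that("dilution correction converts stock additions to concentrations", {
  # 2 uL of 1e-3 M stock into 2 mL: ~1e-6 M, slightly less due to dilution
  conc <- dilution_concentrations(c(0, 2, 4), 1e-3, 2)
  expect_identical(conc[1], 0)
  expect_equal(conc[2], 2e-6 * 1e-3 / 2.002e-3, tolerance = 1e-12)
  expect_lt(conc[2], 1e-6)
  # dilution-corrected grids remain valid titration inputs
  t <- titration_series(conc, c(1000, 900, 820))
  expect_s3_class(t, "titration_series")
  expect_error(dilution_concentrations(-1, 1e-3),
               class = "fluorsense_domain_error")
})

test_that("titration, Job and blank data round-trip through their CSV dialects", {
  t <- simulate_titration(seq(0, 3e-7, length.out = 8), "dynamic_SV",
                          Ksv = 6.52e6, I0 = 1000, noise_sd = 5, seed = 9)
  pt <- tempfile(fileext = ".csv")
  write_titration_csv(t, pt)
  t2 <- read_titration_csv(pt)
  expect_equal(t2$conc, t$conc, tolerance = 1e-9)
  expect_equal(t2$intensity, t$intensity, tolerance = 1e-9)
  expect_equal(t2$I0, t$I0)

  j <- simulate_job_series(1e6, 2e-5, c(1, 1), 11, noise_sd = 0.01, seed = 4)
  pj <- tempfile(fileext = ".csv")
  write_job_csv(j, pj)
  j2 <- read_job_csv(pj)
  expect_equal(j2$signal, j$signal, tolerance = 1e-9)

  pb <- tempfile(fileext = ".csv")
  writeLines(c("intensity", "99.8", "100.2", "100.0"), pb)
  expect_equal(read_blanks_csv(pb), c(99.8, 100.2, 100.0))
})
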