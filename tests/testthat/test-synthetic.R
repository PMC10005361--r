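test_that("quartet construction inverts the quenching formulas", {
  q <- fluorescence_from_targets(0.25, 1, 0.769, 1)
  expect_equal(q$f_m_prime, 0.5)
  expect_equal(q$f_s, 0.375)
  expect_equal(q$f_o, 0.231)
  expect_equal(q$f_m, 1)
  # relaxed quenching: F_m' equals F_m
  expect_equal(fluorescence_from_targets(0.3, 0, 0.7)$f_m_prime, 1)
  expect_error(fluorescence_from_targets(1.2, 1, 0.7),
               class = "phistress_domain_error")
  expect_error(fluorescence_from_targets(0.3, -0.5, 0.7),
               class = "phistress_domain_error")
  expect_error(fluorescence_from_targets(0.3, 1, 0.7, f_m = 0),
               class = "phistress_domain_error")
})

test_that("generators are deterministic under a fixed seed", {
  arch <- cultivar_archetype("roc22")
  a <- simulate_photothermal(arch, seed = 99)
  b <- simulate_photothermal(arch, seed = 99)
  expect_identical(a, b)
  x <- simulate_drought(arch, seed = 99)
  y <- simulate_drought(arch, seed = 99)
  expect_identical(x, y)
  z <- simulate_drought(arch, seed = 100)
  expect_false(identical(x$records, z$records))
})

test_that("the photothermal design reproduces the 30-point calibration layout", {
  arch <- cultivar_archetype("roc16")
  sim <- simulate_photothermal(arch, seed = 1)
  expect_equal(nrow(sim$records), 30) # 3 PAR levels x 10 temperatures
  expect_setequal(unique(sim$records$par), c(285, 625, 1150))
  expect_equal(sum(!sim$records$in_model_range), 6) # 11.8 and 42.7 degC rows
  expect_true(all(sim$records$day_after_drought == 0))
})

test_that("noise-free emission round-trips through parameter derivation", {
  arch <- cultivar_archetype("roc22")
  sim <- simulate_photothermal(arch, sigma_phi = 0, seed = 2)
  d <- chlf_params(sim$records)
  expect_equal(d$phi, sim$truth$phi_true, tolerance = 1e-12)
  expect_equal(d$fvfm, rep(0.769, 30), tolerance = 1e-12)

  simd <- simulate_drought(arch, sigma_phi = 0, sigma_rswc = 0, seed = 2)
  dd <- quiet(chlf_params(simd$records))
  expect_equal(dd$phi, simd$truth$phi_true, tolerance = 1e-12)
  expect_equal(as.numeric(tapply(dd$rswc, dd$day_after_drought, mean)),
               as.numeric(simd$truth$rswc_by_day), tolerance = 1e-12)
})

test_that("drying anchors are honoured and interpolated log-linearly", {
  arch <- cultivar_archetype("roc22")
  sim <- simulate_drought(arch, seed = 3)
  d <- quiet(chlf_params(sim$records))
  day5 <- mean(d$rswc[d$day_after_drought == 5])
  expect_equal(day5, 0.40, tolerance = 0.01) # published day-5 anchor
  r16 <- simulate_drought(cultivar_archetype("roc16"), seed = 3)
  d16 <- quiet(chlf_params(r16$records))
  expect_equal(mean(d16$rswc[d16$day_after_drought == 5]), 0.29,
               tolerance = 0.01)
  # unanchored days interpolate exponential drying between anchors
  mid <- simulate_drought(arch, days = c(1, 2, 3), sigma_rswc = 0, seed = 1)
  got <- unname(mid$truth$rswc_by_day)
  expect_equal(got[2], exp((log(0.83) + log(0.58)) / 2), tolerance = 1e-12)
})

test_that("quenching dynamics respect the cultivar contrast", {
  d22 <- quiet(chlf_params(simulate_drought(cultivar_archetype("roc22"),
                                            seed = 11)$records))
  d16 <- quiet(chlf_params(simulate_drought(cultivar_archetype("roc16"),
                                            seed = 11)$records))
  # the resistant cultivar approaches its high quenching ceiling late in the
  # cycle; the susceptible one stays below 1.3 throughout
  expect_gt(max(d22$npq[d22$day_after_drought >= 5]), 1.5)
  expect_lt(max(d16$npq), 1.3)
})
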