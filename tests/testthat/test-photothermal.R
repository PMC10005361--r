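test_that("parameter containers validate their physical constraints", {
  expect_s3_class(table1_params(), "photothermal_params")
  expect_error(photothermal_params(0.7, 1e-4, 0.7, 1e-4, 0.77, 1e-4,
                                   t_min = 30, t_o = 20, t_max = 40),
               class = "phistress_domain_error")
  expect_error(photothermal_params(1.2, 1e-4, 0.7, 1e-4, 0.77, 1e-4),
               class = "phistress_domain_error")
  expect_error(photothermal_params(0.7, -1e-4, 0.7, 1e-4, 0.77, 1e-4),
               class = "phistress_domain_error")
  expect_error(photothermal_params(0.7, 1e-4, 0.7, 1e-4, 1.0, 1e-4),
               class = "phistress_domain_error")
})

test_that("base curves follow the exponential PAR envelopes", {
  p <- table1_params()
  bc0 <- base_curves(0, p)
  expect_equal(bc0$phi_to, 0.769) # dark-adapted maximum at PAR = 0
  expect_equal(bc0$phi_bl, 0.688)
  expect_equal(base_curves(285, p)$phi_bl, 0.688 * exp(-6.77e-4 * 285))
  expect_equal(base_curves(625, p)$phi_to, 0.769 * exp(-5.91e-4 * 625))
  # monotone decay towards zero
  bc <- base_curves(seq(0, 20000, by = 500), p)
  expect_true(all(diff(bc$phi_bl) < 0))
  expect_lt(bc$phi_to[nrow(bc)], 1e-4)
  expect_error(base_curves(-1, p), class = "phistress_domain_error")
})

test_that("temperature response interpolates sinusoidally between base curves", {
  p <- table1_params()
  # optimum: both branches give the optimum envelope
  for (par in c(0, 285, 1150)) {
    expect_equal(phi_photothermal(30, par, p), base_curves(par, p)$phi_to)
  }
  # cardinal endpoints give the base yields
  expect_equal(phi_photothermal(15, 285, p), base_curves(285, p)$phi_bl)
  expect_equal(phi_photothermal(40, 285, p), base_curves(285, p)$phi_bh)
  # interior lower-branch value at PAR = 0
  expect_equal(phi_photothermal(22.5, 0, p),
               0.688 + (0.769 - 0.688) * sin(pi / 4))
  expect_error(phi_photothermal(10, 285, p), class = "phistress_domain_error")
  expect_error(phi_photothermal(45, 285, p), class = "phistress_domain_error")
})

test_that("the yield surface is continuous and unimodal in temperature", {
  p <- table1_params()
  for (par in c(0, 285, 625, 1150)) {
    h <- 1e-8
    expect_equal(phi_photothermal(30 - h, par, p),
                 phi_photothermal(30 + h, par, p), tolerance = 1e-6)
    tt <- seq(15, 40, by = 0.25)
    phi <- phi_photothermal(tt, par, p)
    expect_true(all(diff(phi[tt <= 30]) >= 0))
    expect_true(all(diff(phi[tt >= 30]) <= 0))
  }
  # higher cold than heat sensitivity: Phi_bL < Phi_bH at PAR > 0
  for (par in c(285, 625, 1150)) {
    bc <- base_curves(par, p)
    expect_lt(bc$phi_bl, bc$phi_bh)
  }
})

test_that("noise-free data is recovered exactly by both fitting strategies", {
  p <- table1_params()
  design <- expand.grid(temp = seq(16, 39.5, length.out = 10),
                        par = c(285, 625, 1150))
  design$phi <- phi_photothermal(design$temp, design$par, p)
  truth <- c(a_l = 0.688, b_l = 6.77e-4, a_h = 0.676, b_h = 5.16e-4,
             eps = 5.91e-4)
  joint <- fit_photothermal(design, fvfm = 0.769)
  expect_equal(coef(joint), truth, tolerance = 1e-5)
  expect_lt(joint$sse, 1e-10)
  two <- fit_photothermal(design, fvfm = 0.769, method = "two_stage")
  expect_equal(coef(two), truth, tolerance = 1e-5)
  # joint and two-stage agree on noise-free data
  expect_equal(coef(joint), coef(two), tolerance = 1e-5)
  expect_equal(predict(joint, design), design$phi, tolerance = 1e-5)
})

test_that("degenerate designs raise underdetermined errors", {
  p <- table1_params()
  one_par <- data.frame(temp = seq(16, 39, length.out = 10), par = 625)
  one_par$phi <- phi_photothermal(one_par$temp, one_par$par, p)
  expect_error(fit_photothermal(one_par, fvfm = 0.769),
               class = "phistress_underdetermined_error")
  tiny <- data.frame(temp = c(20, 35), par = c(285, 625),
                     phi = c(0.6, 0.5))
  expect_error(fit_photothermal(tiny, fvfm = 0.769),
               class = "phistress_underdetermined_error")
  cold_only <- expand.grid(temp = seq(16, 28, length.out = 6),
                           par = c(285, 1150))
  cold_only$phi <- phi_photothermal(cold_only$temp, cold_only$par, p)
  expect_error(fit_photothermal(cold_only, fvfm = 0.769),
               class = "phistress_underdetermined_error")
})

test_that("out-of-range temperatures are excluded with a warning", {
  p <- table1_params()
  design <- expand.grid(temp = c(11.8, seq(16, 39.5, length.out = 8), 42.7),
                        par = c(285, 625, 1150))
  design$phi <- 0.5
  design$phi[design$temp >= 15 & design$temp <= 40] <- phi_photothermal(
    design$temp[design$temp >= 15 & design$temp <= 40],
    design$par[design$temp >= 15 & design$temp <= 40], p
  )
  expect_warning(fit <- fit_photothermal(design, fvfm = 0.769),
                 "outside")
  expect_equal(fit$n, 24)
  expect_equal(coef(fit)[["eps"]], 5.91e-4, tolerance = 1e-5)
})

test_that("fit methods expose the standard modelling interface", {
  p <- table1_params()
  sim <- simulate_photothermal(cultivar_archetype("roc22"), seed = 3)
  d <- derived_photothermal(sim)
  fit <- quiet(fit_photothermal(d[c("temp", "par", "phi")], fvfm = 0.769))
  expect_s3_class(fit, "photothermal_fit")
  expect_named(coef(fit), c("a_l", "b_l", "a_h", "b_h", "eps"))
  expect_length(residuals(fit), fit$n)
  expect_equal(fitted(fit) + residuals(fit), fit$data$phi)
  s <- summary(fit)
  expect_s3_class(s, "summary.photothermal_fit")
  expect_output(print(s), "Std. Error")
  expect_output(print(fit), "Photothermal")
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_equal(dim(sims), c(fit$n, 2))
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(fit))
})
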