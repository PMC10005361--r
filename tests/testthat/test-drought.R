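roc22_dp <- function() cultivar_archetype("roc22")$drought

test_that("the stress index is baseline above and exponential below the changepoint", {
  dp <- roc22_dp()
  expect_equal(epsilon_d(0.8, dp), 5.91) # scaled well-watered coefficient
  expect_equal(epsilon_d(0.29, dp), 5.91 + 39.63 * exp(-10.01 * 0.29))
  expect_equal(epsilon_d(0.41, dp), 5.91) # just above the changepoint
  # non-increasing in rswc below the changepoint
  rr <- seq(0, dp$rswc_c, by = 0.01)
  expect_true(all(diff(epsilon_d(rr, dp)) <= 0))
  expect_error(epsilon_d(1.2, dp), class = "phistress_domain_error")
  expect_error(epsilon_d(-0.1, dp), class = "phistress_domain_error")
  expect_error(drought_params(-1, 10, 0.4, table1_params()),
               class = "phistress_domain_error")
  expect_error(drought_params(39, 10, 1.4, table1_params()),
               class = "phistress_domain_error")
})

test_that("drought attenuation reduces to the well-watered model when unstressed", {
  dp <- roc22_dp()
  tt <- c(16, 22, 30, 36, 39.5)
  pp <- c(0, 150, 625, 1150)
  g <- expand.grid(temp = tt, par = pp)
  # above the changepoint: exact equality
  expect_equal(phi_drought(g$temp, g$par, 0.8, dp),
               phi_photothermal(g$temp, g$par, dp$base))
  # PAR = 0: drought has no effect at any water status
  for (rswc in c(0.05, 0.2, 0.39)) {
    expect_equal(phi_drought(30, 0, rswc, dp),
                 phi_photothermal(30, 0, dp$base))
  }
  # below the changepoint at PAR > 0: strictly attenuated
  dry <- expand.grid(temp = tt, par = pp[pp > 0])
  expect_true(all(phi_drought(dry$temp, dry$par, 0.2, dp) <
                    phi_photothermal(dry$temp, dry$par, dp$base)))
})

test_that("the attenuated optimum envelope matches the index-substituted exponential", {
  dp <- roc22_dp()
  # at the optimum temperature the yield is fvfm * exp(-eps_D * 1e-4 * PAR)
  for (rswc in c(0.17, 0.25, 0.35)) {
    ed <- epsilon_d(rswc, dp)
    expect_equal(phi_drought(30, 1150, rswc, dp),
                 0.769 * exp(-ed * 1e-4 * 1150))
  }
  # eps_D = 13 (severe-band boundary) worked example
  rswc13 <- -log((13 - 5.91) / 39.63) / 10.01
  expect_equal(epsilon_d(rswc13, dp), 13, tolerance = 1e-12)
  expect_equal(phi_drought(30, 1150, rswc13, dp),
               0.769 * exp(-13e-4 * 1150), tolerance = 1e-9)
})

test_that("the literal base-curve attenuation is kept distinct from the ratio form", {
  dp <- roc22_dp()
  ratio <- phi_drought(22, 625, 0.8, dp)
  literal <- phi_drought(22, 625, 0.8, dp, attenuation = "literal")
  # the literal reading does not reduce to the well-watered model
  expect_lt(literal, ratio)
  expect_equal(ratio, phi_photothermal(22, 625, dp$base))
})

test_that("index inversion round-trips the forward model", {
  dp <- roc22_dp()
  set.seed(42)
  n <- 60
  temp <- runif(n, 16, 39)
  par <- runif(n, 60, 1200)
  rswc <- runif(n, 0.05, 0.39)
  eps_true <- epsilon_d(rswc, dp)
  phi <- phi_drought(temp, par, rswc, dp)
  eps_hat <- invert_epsilon_d(phi, temp, par, dp)
  expect_equal(eps_hat, eps_true, tolerance = 1e-6)
  # no-stress limit: the well-watered yield maps to the baseline index
  expect_warning(
    e0 <- invert_epsilon_d(phi_photothermal(25, 625, dp$base), 25, 625, dp),
    "clamped"
  )
  expect_equal(e0, 5.91)
})

test_that("index inversion enforces its identifiability preconditions", {
  dp <- roc22_dp()
  expect_error(invert_epsilon_d(0.4, 25, 20, dp),
               class = "phistress_domain_error") # par below par_min
  phi_ww <- phi_photothermal(25, 625, dp$base)
  expect_error(invert_epsilon_d(phi_ww + 0.05, 25, 625, dp),
               class = "phistress_inversion_error")
  # generous tolerance clamps instead
  expect_warning(
    expect_equal(invert_epsilon_d(phi_ww + 0.05, 25, 625, dp,
                                  noise_tol = Inf), 5.91)
  )
  expect_error(invert_epsilon_d(0.05, 25, 50, dp),
               class = "phistress_bracket_error")
})

test_that("noise-free drought data is recovered exactly", {
  for (name in c("roc22", "roc16")) {
    arch <- cultivar_archetype(name)
    sim <- simulate_drought(arch, sigma_phi = 0, sigma_rswc = 0)
    d <- quiet(chlf_params(sim$records))
    fit <- quiet(fit_drought(d, base = arch$photothermal))
    truth <- sim$truth$drought
    expect_equal(coef(fit)[["rswc_c"]], truth$rswc_c, tolerance = 1e-6)
    expect_equal(coef(fit)[["c"]], truth$c, tolerance = 1e-3)
    expect_equal(coef(fit)[["d"]], truth$d, tolerance = 1e-3)
    expect_lt(fit$sse, 1e-6)
  }
})

test_that("data without index elevation leaves the changepoint unidentifiable", {
  p <- table1_params()
  set.seed(9)
  wet <- data.frame(temp = runif(40, 20, 38), par = runif(40, 100, 1200),
                    rswc = runif(40, 0.5, 0.95))
  wet$phi <- phi_photothermal(wet$temp, wet$par, p)
  expect_error(quiet(fit_drought(wet, base = p)),
               class = "phistress_changepoint_error")
  # same conclusion with observation noise on the yield
  wet$phi <- pmin(0.999, pmax(0.001, wet$phi + rnorm(40, 0, 0.02)))
  expect_error(quiet(fit_drought(wet, base = p)),
               class = "phistress_changepoint_error")
})

test_that("drought fit exposes the standard modelling interface", {
  arch <- cultivar_archetype("roc22")
  fit <- fit_drought_sim(arch, seed = 2)
  expect_s3_class(fit, "drought_fit")
  expect_named(coef(fit), c("c", "d", "rswc_c"))
  expect_s3_class(fit$params, "drought_params")
  expect_gt(fit$n_excluded_par, 0) # the PAR = 0 ramp step is excluded
  pred <- predict(fit)
  expect_length(pred, fit$n)
  expect_true(all(pred > 0 & pred < 1))
  expect_length(predict(fit, type = "eps_d"), fit$n)
  expect_output(print(fit), "rswc_c")
  expect_output(print(summary(fit)), "stage counts")
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(fit))
})

test_that("drought stages map the index onto the published severity bands", {
  expect_equal(as.character(drought_stage(5.91)), "well_watered")
  expect_equal(as.character(drought_stage(10)), "moderate")
  expect_equal(as.character(drought_stage(14)), "severe")
  # boundaries belong to the more severe stage
  expect_equal(as.character(drought_stage(c(7, 9, 13))),
               c("slight", "moderate", "severe"))
  # monotone: larger index never maps to a milder stage
  x <- sort(runif(200, 0, 30))
  expect_true(all(diff(as.integer(drought_stage(x))) >= 0))
  expect_error(drought_stage(-1), class = "phistress_domain_error")
})
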