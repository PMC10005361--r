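test_that("F_o' follows the light-adapted minimal-fluorescence estimate", {
  expect_equal(fo_prime(0.2, 0.769, 0.5), 0.2 / (0.769 + 0.4))
  expect_equal(fo_prime(0.3, 0.7, 0.3), 0.3 / (0.7 + 1.0))
  # scale equivariance: units cancel in the ratio term
  expect_equal(fo_prime(0.4, 0.769, 1.0), 2 * fo_prime(0.2, 0.769, 0.5))
  # always below f_m_prime
  set.seed(11)
  fo <- runif(50, 0.05, 0.5)
  fmp <- fo + runif(50, 0.05, 1)
  fv <- runif(50, 0.3, 0.9)
  expect_true(all(fo_prime(fo, fv, fmp) < fmp))
  expect_true(all(fo_prime(fo, fv, fmp) > 0))

  expect_error(fo_prime(-0.1, 0.7, 0.5), class = "phistress_domain_error")
  expect_error(fo_prime(0.2, 1.0, 0.5), class = "phistress_domain_error")
  expect_error(fo_prime(0.2, 0.7, 0), class = "phistress_domain_error")
})

test_that("quenching parameters match their defining fluorescence ratios", {
  # NPQ = F_m/F_m' - 1 and Phi = (F_m' - F_s)/F_m'
  rec <- data.frame(f_s = 0.45, f_m_prime = 0.6, f_o = 0.231, f_m = 1.0)
  d <- chlf_params(rec)
  expect_equal(d$phi, 0.25)
  expect_equal(d$npq, 1 / 0.6 - 1)
  expect_equal(d$fvfm, 0.769) # the well-watered dark-adapted value
  rec2 <- data.frame(f_s = 0.3, f_m_prime = 0.5, f_o = 0.2, f_m = 1.0)
  expect_equal(chlf_params(rec2)$npq, 1.0)

  # dark-relaxed limit (NPQ = 0, q_L = 1): Phi_NO collapses to F_o/F_m
  dark <- data.frame(f_s = 0.231, f_m_prime = 1, f_o = 0.231, f_m = 1)
  dd <- chlf_params(dark)
  expect_equal(dd$npq, 0)
  expect_equal(dd$q_l, 1)
  expect_equal(dd$phi_no, 0.231)
})

test_that("derived parameters are invariant under uniform signal rescaling", {
  q <- random_quartets(40, seed = 5)
  d1 <- quiet(chlf_params(q))
  for (scale in c(0.1, 3.7)) {
    d2 <- quiet(chlf_params(q * scale))
    for (col in c("phi", "fvfm", "npq", "q_l", "phi_no")) {
      expect_equal(d2[[col]], d1[[col]], tolerance = 1e-12)
    }
    expect_equal(d2$f_o_prime, d1$f_o_prime * scale, tolerance = 1e-12)
  }
})

test_that("target round trip recovers (phi, npq, fvfm) to near machine precision", {
  set.seed(21)
  phi <- runif(60, 0.02, 0.9)
  npq <- runif(60, 0, 3)
  fvfm <- runif(60, 0.4, 0.9)
  q <- fluorescence_from_targets(phi, npq, fvfm, f_m = runif(60, 0.5, 2))
  d <- quiet(chlf_params(q))
  expect_equal(d$phi, phi, tolerance = 1e-12)
  expect_equal(d$npq, npq, tolerance = 1e-12)
  expect_equal(d$fvfm, fvfm, tolerance = 1e-12)
})

test_that("Phi_NO decreases as nonphotochemical quenching grows", {
  npq <- seq(0, 3, by = 0.25)
  q <- fluorescence_from_targets(0.3, npq, 0.769)
  d <- chlf_params(q)
  expect_true(all(diff(d$phi_no) < 0))
})

test_that("relative substrate water content is the saturation-normalized ratio", {
  expect_equal(rel_swc(38, 38), 1.0)
  expect_equal(rel_swc(15.2, 38), 0.4)
  expect_equal(rel_swc(0, 38), 0.0)
  expect_error(rel_swc(40, 38), class = "phistress_validation_error")
  expect_error(rel_swc(10, 0), class = "phistress_domain_error")
  expect_error(rel_swc(-1, 38), class = "phistress_domain_error")
})

test_that("invalid fluorescence records are rejected with row context", {
  bad <- data.frame(f_s = c(0.4, 0.4), f_m_prime = c(0.6, 0.6),
                    f_o = c(0.3, 0.7), f_m = c(1, 0.65))
  expect_error(chlf_params(bad), "row", class = "phistress_validation_error")
  # F_m' < F_s
  bad2 <- data.frame(f_s = 0.7, f_m_prime = 0.6, f_o = 0.2, f_m = 1)
  expect_error(chlf_params(bad2), class = "phistress_validation_error")
  # phi > fvfm beyond tolerance warns but keeps the record
  odd <- fluorescence_from_targets(0.9, 0.5, 0.6)
  expect_warning(chlf_params(odd), "phi > fvfm")
  expect_silent(chlf_params(fluorescence_from_targets(0.5, 0.5, 0.6)))
})
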