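# shared fixtures and quiet wrappers; everything is generated in code

table1_params <- function() {
  photothermal_params(
    a_l = 0.688, b_l = 6.77e-4, a_h = 0.676, b_h = 5.16e-4,
    fvfm = 0.769, eps = 5.91e-4
  )
}

quiet <- function(expr) {
  suppressMessages(suppressWarnings(expr))
}

# derive + in-range filter for a simulated photothermal bundle
derived_photothermal <- function(sim) {
  d <- quiet(chlf_params(sim$records))
  d[d$in_model_range, , drop = FALSE]
}

fit_drought_sim <- function(arch, seed, ...) {
  sim <- simulate_drought(arch, seed = seed, ...)
  d <- quiet(chlf_params(sim$records))
  quiet(fit_drought(d, base = arch$photothermal,
                    group = d$day_after_drought))
}

random_quartets <- function(n, seed) {
  set.seed(seed)
  fluorescence_from_targets(
    phi = runif(n, 0.05, 0.75),
    npq = runif(n, 0, 2.5),
    fvfm = runif(n, 0.5, 0.85),
    f_m = runif(n, 0.5, 2)
  )
}
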