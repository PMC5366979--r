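test_that("initial_guess brackets the truth and orders the seeds", {
  # single-Debye spectrum: seed tau within a decade of the true value
  true_tau <- 9.4e-12
  sp <- simulate_spectrum(fixture_model("water_293K"), band_preset("tdr"),
                          noise_spec(0))
  g <- initial_guess(sp, 1)
  expect_lt(abs(log10(g$processes[[1]]$tau / true_tau)), 1)

  # three seeds: distinct, descending tau, labelled L/M/H
  g3 <- initial_guess(sp, 3)
  taus <- sapply(g3$processes, `[[`, "tau")
  expect_length(unique(taus), 3)
  expect_true(all(diff(taus) < 0))
  expect_equal(sapply(g3$processes, `[[`, "label"), c("L", "M", "H"))

  # degenerate flat spectrum is rejected
  flat <- permittivity_spectrum(c(1e9, 1e10, 1e11), c(5, 5, 5), c(0, 0, 0))
  expect_error(initial_guess(flat, 1), "degenerate")
  # sub-decade span is rejected
  narrow <- permittivity_spectrum(c(1e9, 2e9), c(70, 60), c(10, 20))
  expect_error(initial_guess(narrow, 1), "decade")
})

test_that("noiseless three-process spectra are recovered exactly", {
  truth <- fixture_model("glycine_solution")
  sp <- simulate_spectrum(truth, band_preset("tdr"), noise_spec(0))
  fit <- fit_relaxation(sp, config = fast_fit())
  expect_true(fit$converged)
  for (k in 1:3) {
    expect_equal(fit$model$processes[[k]]$delta_eps,
                 truth$processes[[k]]$delta_eps, tolerance = 1e-3)
    expect_equal(fit$model$processes[[k]]$tau,
                 truth$processes[[k]]$tau, tolerance = 1e-3)
  }
  expect_equal(fit$model$eps_inf, truth$eps_inf, tolerance = 1e-3)
  # labels follow descending tau
  expect_equal(sapply(fit$model$processes, `[[`, "label"),
               c("L", "M", "H"))
  # positivity is structural
  expect_true(all(sapply(fit$model$processes, `[[`, "delta_eps") > 0))
  expect_true(all(sapply(fit$model$processes, `[[`, "tau") > 0))
})

test_that("single-process water fit recovers the static permittivity", {
  truth <- fixture_model("water_293K")
  sp <- simulate_spectrum(truth, band_preset("tdr"), noise_spec(0))
  fit <- fit_relaxation(sp, config = fast_fit(1))
  expect_equal(static_permittivity(fit$model), static_permittivity(truth),
               tolerance = 5e-3)
})

test_that("refitting from a solution is a fixed point", {
  sp <- simulate_spectrum(fixture_model("glycine_solution"),
                          band_preset("tdr"), noise_spec(0.03, seed = 11))
  fit <- fit_relaxation(sp, config = fast_fit())
  refit <- fit_relaxation(sp, config = fast_fit(n_starts = 1),
                          start = fit$model)
  expect_equal(coef(refit), coef(fit), tolerance = 1e-6)
})

test_that("fit object methods are coherent", {
  truth <- fixture_model("water_293K")
  sp <- simulate_spectrum(truth, band_preset("tdr"),
                          noise_spec(0.03, seed = 3))
  fit <- fit_relaxation(sp, config = fast_fit(1))
  # coef names and values
  cf <- coef(fit)
  expect_named(cf, c("eps_inf", "delta_eps_L", "tau_L"))
  # residuals = data - fitted
  r <- residuals(fit)
  f <- fitted(fit)
  expect_equal(r[, "eps_real"], sp$eps_real - f$eps_real)
  # predict on a new grid evaluates the fitted model
  newf <- c(1e9, 5e9)
  expect_equal(predict(fit, newf)$eps_real,
               evaluate_model(fit$model, newf)$eps_real)
  # simulate returns spectra on the data grid, deterministic by seed
  sims <- simulate(fit, nsim = 2, seed = 9)
  expect_equal(sims[[1]]$frequency, sp$frequency)
  expect_equal(simulate(fit, seed = 9)[[1]]$eps_real, sims[[1]]$eps_real)
  # standard errors exist on the natural scale
  expect_true(all(is.finite(fit$std_errors)))
  # summary table aligns estimates with their errors
  s <- summary(fit)
  expect_equal(s$table["tau_L", "estimate"], unname(cf["tau_L"]))
})

test_that("model comparison prefers truth over both under- and over-fitting", {
  # generated with 3 processes: n = 3 beats n = 2. The small intermediate
  # process changes the spectrum by only ~0.1% RMS over this band, so the
  # check runs noiseless, where the extra process is unambiguous.
  sp3 <- simulate_spectrum(fixture_model("glycine_solution"),
                           band_preset("tdr"), noise_spec(0))
  cmp <- compare_models(sp3, list(fast_fit(2, n_starts = 5),
                                  fast_fit(3, n_starts = 5)))
  expect_equal(cmp$ranking[1], 2L)

  # generated with 1 process: the parsimony penalty picks n = 1 over n = 3
  sp1 <- simulate_spectrum(fixture_model("water_293K"),
                           band_preset("tdr"), noise_spec(0.02, seed = 5))
  cmp1 <- compare_models(sp1, list(fast_fit(1), fast_fit(3)))
  expect_equal(cmp1$ranking[1], 1L)

  # identical configs give identical reports, stable order
  cmp2 <- compare_models(sp1, list(fast_fit(1), fast_fit(1)))
  expect_equal(coef(cmp2$fits[[1]]), coef(cmp2$fits[[2]]))
  expect_equal(cmp2$ranking, c(1L, 2L))

  expect_error(compare_models(sp1, list(fast_fit(1))), "at least two")
})

test_that("dc-conductivity contamination is detected and co-fitted", {
  truth <- relaxation_model(5.3,
    list(debye_process(28.7, 72e-12, "L"), debye_process(82, 9.8e-12, "H")),
    sigma_dc = 0.08)
  sp <- simulate_spectrum(truth, band_preset("tdr"), noise_spec(0))
  fit <- fit_relaxation(sp, config = fit_config(2, conductivity = "auto",
                                                seed = 1, n_starts = 3))
  expect_gt(fit$model$sigma_dc, 0)
  expect_equal(fit$model$sigma_dc, 0.08, tolerance = 0.05)
  expect_equal(fit$model$processes[[1]]$tau, 72e-12, tolerance = 0.02)

  # clean spectrum under "auto": no conductivity term added
  clean <- simulate_spectrum(relaxation_model(5.3,
    list(debye_process(82, 9.8e-12, "H"))), band_preset("tdr"),
    noise_spec(0))
  fit0 <- fit_relaxation(clean, config = fit_config(1, conductivity = "auto",
                                                    n_starts = 2))
  expect_equal(fit0$model$sigma_dc, 0)
})

test_that("a spectrum shorter than twice the parameter count is refused", {
  sp <- permittivity_spectrum(10^seq(8.7, 10.4, length.out = 6),
                              seq(80, 10, length.out = 6),
                              rep(10, 6))
  expect_error(fit_relaxation(sp, config = fast_fit(3)), "too short")
})
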