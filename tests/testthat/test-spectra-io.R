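test_that("spectrum constructor validates and sorts", {
  sp <- permittivity_spectrum(c(2e9, 1e9, 3e9), c(70, 75, 64), c(18, 10, 24))
  expect_identical(sp$frequency, c(1e9, 2e9, 3e9))
  expect_identical(sp$eps_real, c(75, 70, 64))
  expect_identical(sp$eps_imag, c(10, 18, 24))
  expect_equal(length(sp), 3L)

  expect_error(permittivity_spectrum(c(1e9, 1e9), c(1, 1), c(0, 0)),
               "duplicate")
  expect_error(permittivity_spectrum(c(0, 1e9), c(1, 1), c(0, 0)),
               "positive")
  expect_error(permittivity_spectrum(1e9, c(1, 2), 0), "equal length")
  expect_error(permittivity_spectrum(1e9, 75, -0.5), "non-negative")
  expect_error(permittivity_spectrum(numeric(0), numeric(0), numeric(0)),
               "at least one")
})

test_that("complex_permittivity uses the eps' - i eps'' convention", {
  sp <- permittivity_spectrum(1e9, 75, 10)
  expect_equal(complex_permittivity(sp), complex(real = 75, imaginary = -10))
})

test_that("read_spectrum parses, sorts and validates delimited text", {
  tf <- write_spectrum_csv(c("# synthetic example",
                             "frequency_hz,eps_real,eps_imag",
                             "2e9,70,18", "1e9,75,10", "3e9,64,24"))
  sp <- read_spectrum(tf)
  expect_identical(sp$frequency, c(1e9, 2e9, 3e9))
  expect_identical(sp$eps_real, c(75, 70, 64))

  # custom column names
  tf2 <- write_spectrum_csv(c("f,eps1,eps2", "1e9,75,10", "2e9,70,18"))
  sp2 <- read_spectrum(tf2, columns = c(frequency = "f", eps_real = "eps1",
                                        eps_imag = "eps2"))
  expect_identical(sp2$frequency, c(1e9, 2e9))

  # errors: missing column, negative loss, negative frequency, no file
  expect_error(read_spectrum(tf2), "missing column")
  tf3 <- write_spectrum_csv(c("frequency_hz,eps_real,eps_imag",
                              "1e9,75,-0.5"))
  expect_error(read_spectrum(tf3), "non-negative")
  tf4 <- write_spectrum_csv(c("frequency_hz,eps_real,eps_imag",
                              "-1e9,75,1"))
  expect_error(read_spectrum(tf4), "positive")
  expect_error(read_spectrum(tempfile()), "not found")
})

test_that("spectrum write/read is the identity", {
  sp <- evaluate_model(fixture_model("glycine_solution"),
                       make_grid(band_preset("tdr")))
  tf <- tempfile(fileext = ".csv")
  write_spectrum(sp, tf)
  back <- read_spectrum(tf)
  expect_equal(back$frequency, sp$frequency)
  expect_equal(back$eps_real, sp$eps_real, tolerance = 1e-12)
  expect_equal(back$eps_imag, sp$eps_imag, tolerance = 1e-12)
})

test_that("fit report JSON round-trips models to full precision", {
  model <- relaxation_model(
    5.3, list(debye_process(28.7, 7.2e-11, "L"),
              debye_process(4.123456789e0, 2.5e-11, "M"),
              debye_process(82, 9.8e-12, "H")),
    sigma_dc = 0.05)
  tf <- tempfile(fileext = ".json")
  write_report(model, tf)
  back <- read_report(tf)
  expect_equal(back$model$eps_inf, model$eps_inf)
  expect_equal(back$model$sigma_dc, model$sigma_dc)
  for (k in 1:3) {
    expect_identical(back$model$processes[[k]]$delta_eps,
                     model$processes[[k]]$delta_eps)
    expect_identical(back$model$processes[[k]]$tau,
                     model$processes[[k]]$tau)
    expect_identical(back$model$processes[[k]]$label,
                     model$processes[[k]]$label)
  }

  # picosecond convenience field: tau 7.2e-11 s -> 72 ps
  raw <- jsonlite::read_json(tf)
  expect_equal(raw$model$processes[[1]]$tau_ps, 72)

  # degenerate: empty model survives the round trip
  empty <- relaxation_model(5.3)
  tf2 <- tempfile(fileext = ".json")
  write_report(empty, tf2)
  expect_length(read_report(tf2)$model$processes, 0)
})

test_that("fit reports carry diagnostics through JSON", {
  sp <- simulate_spectrum(fixture_model("water_293K"), band_preset("tdr"),
                          noise_spec(0))
  fit <- fit_relaxation(sp, n_processes = 1, n_starts = 1)
  tf <- tempfile(fileext = ".json")
  write_report(fit, tf)
  back <- read_report(tf)
  expect_true(back$diagnostics$converged)
  expect_equal(back$diagnostics$residual_rms_real, fit$residual_rms_real)
  expect_equal(back$model$processes[[1]]$tau, fit$model$processes[[1]]$tau)
})

test_that("the packaged synthetic example spectrum loads and fits", {
  path <- system.file("extdata", "glycine_tdr_synthetic.csv",
                      package = "dielax")
  sp <- read_spectrum(path, band_label = "TDR")
  expect_length(sp, 18)
  expect_equal(sp$frequency[1], 5e8)
  fit <- fit_relaxation(sp, config = fast_fit(3))
  expect_true(fit$converged)
  # the slow process of the generating model sits near 72 ps
  expect_equal(fit$model$processes[[1]]$tau, 72e-12, tolerance = 0.25)
})
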