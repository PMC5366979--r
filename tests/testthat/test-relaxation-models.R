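test_that("debye_term matches the closed form at key frequencies", {
  p <- debye_process(28.7, 72e-12, "L")
  # zero frequency: the full strength, no loss
  expect_equal(debye_term(p, 0), complex(real = 28.7, imaginary = 0))
  # omega*tau = 1: half strength, equal loss
  f_peak <- 1 / (2 * pi * 72e-12)
  expect_equal(debye_term(p, f_peak),
               complex(real = 14.35, imaginary = -14.35))
  # arbitrary point against direct complex arithmetic
  p2 <- debye_process(75.2, 72e-12)
  x <- 2 * pi * 1e9 * 72e-12
  oracle <- 75.2 / complex(real = 1, imaginary = x)
  expect_equal(debye_term(p2, 1e9), oracle)
  expect_equal(Re(oracle), 62.42, tolerance = 1e-3)
  expect_equal(Im(oracle), -28.24, tolerance = 1e-3)

  expect_error(debye_term(p, -1e9), "non-negative")
})

test_that("process and model constructors enforce invariants", {
  expect_error(debye_process(-1, 1e-12), "delta_eps")
  expect_error(debye_process(1, 0), "tau")
  expect_error(debye_process(1, 1e-12, alpha = 1), "alpha")
  expect_error(relaxation_model(0.5), "eps_inf")
  expect_error(relaxation_model(5, sigma_dc = -1), "sigma_dc")
  expect_error(relaxation_model(5, list(debye_process(1, 1e-12, "L"),
                                        debye_process(1, 2e-12, "L"))),
               "unique")
  # processes stored by descending tau regardless of input order
  m <- relaxation_model(5, list(debye_process(1, 1e-12, "H"),
                                debye_process(1, 7e-11, "L")))
  expect_equal(m$processes[[1]]$label, "L")
})

test_that("evaluate_model sums terms and handles edge cases", {
  grid <- make_grid(band_preset("tdr"))
  # empty model: flat eps', zero loss
  flat <- evaluate_model(relaxation_model(5.3), grid)
  expect_true(all(flat$eps_real == 5.3) && all(flat$eps_imag == 0))

  # additivity: two-process model = sum of single-process models - eps_inf
  pA <- debye_process(28.7, 72e-12, "L"); pB <- debye_process(75, 9.4e-12, "H")
  m2 <- evaluate_model(relaxation_model(5, list(pA, pB)), grid)
  mA <- evaluate_model(relaxation_model(5, list(pA)), grid)
  mB <- evaluate_model(relaxation_model(5, list(pB)), grid)
  expect_equal(m2$eps_real, mA$eps_real + mB$eps_real - 5)
  expect_equal(m2$eps_imag, mA$eps_imag + mB$eps_imag)

  # loss-peak closed form: at f = 1/(2 pi tau), eps' = eps_inf + deps/2
  tau <- 9.4e-12
  m <- evaluate_model(relaxation_model(5, list(debye_process(75.2, tau))),
                      1 / (2 * pi * tau))
  expect_equal(m$eps_real, 5 + 75.2 / 2, tolerance = 1e-12)
  expect_equal(m$eps_imag, 75.2 / 2, tolerance = 1e-12)
})

test_that("static permittivity is eps_inf plus the summed strengths", {
  gly <- relaxation_model(91.3, list(debye_process(28.7, 72e-12, "L")))
  expect_equal(static_permittivity(gly), 120)
  expect_equal(static_permittivity(relaxation_model(7.5)), 7.5)
  expect_equal(static_permittivity(
    relaxation_model(5, list(debye_process(75, 1e-11),
                             debye_process(10, 1e-10)))), 90)
})

test_that("conduction-free models are monotone with non-negative loss", {
  set.seed(42)
  grid <- 10^seq(8, 13, length.out = 60)
  for (i in 1:20) {
    n <- sample(1:4, 1)
    procs <- lapply(seq_len(n), function(k)
      debye_process(runif(1, 0.5, 80), 10^runif(1, -12.5, -9.5)))
    m <- relaxation_model(runif(1, 1, 10), procs)
    sp <- evaluate_model(m, grid)
    expect_true(all(diff(sp$eps_real) <= 1e-12))
    expect_true(all(sp$eps_imag >= 0))
    # low-frequency limit approaches eps_s
    lo <- evaluate_model(m, 1e-2 / (2 * pi * max(sapply(procs, `[[`, "tau"))))
    expect_equal(lo$eps_real, static_permittivity(m), tolerance = 1e-3)
  }
})

test_that("dc conductivity adds sigma/(2 pi f eps0) to the loss only", {
  eps0 <- 8.85418781e-12
  m0 <- relaxation_model(5, list(debye_process(75, 9.4e-12)))
  m1 <- relaxation_model(5, list(debye_process(75, 9.4e-12)), sigma_dc = 0.1)
  f <- c(5e8, 1e9, 1e10)
  s0 <- evaluate_model(m0, f); s1 <- evaluate_model(m1, f)
  expect_equal(s1$eps_real, s0$eps_real)
  expect_equal(s1$eps_imag - s0$eps_imag, 0.1 / (2 * pi * f * eps0))
  expect_error(evaluate_model(m1, c(0, 1e9)), "sigma_dc > 0")
})

test_that("Cole-Cole broadening reduces to Debye at alpha = 0", {
  f <- 10^seq(8, 12, length.out = 40)
  p0 <- debye_process(30, 7e-11, alpha = 0)
  pc <- debye_process(30, 7e-11, alpha = 0.2)
  expect_equal(debye_term(p0, f), 30 / complex(real = 1,
                                               imaginary = 2 * pi * f * 7e-11))
  # broadening lowers and widens the loss peak but keeps the strength
  expect_equal(Re(debye_term(pc, 0)), 30)
  expect_lt(max(-Im(debye_term(pc, f))), max(-Im(debye_term(p0, f))))
})
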