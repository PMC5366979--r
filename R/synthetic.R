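#' Frequency band specification
#'
#' A log-spaced measurement band. The built-in presets match the two
#' instruments whose coverage the synthetic spectra emulate: `"tdr"`
#' (time-domain reflectometry, 500 MHz - 25 GHz) and `"thz"` (terahertz
#' time-domain spectroscopy, 300 GHz - 2.5 THz).
#'
#' @param f_min,f_max band edges in Hz, `0 < f_min < f_max`.
#' @param points_per_decade grid density (default 10).
#' @return object of class `"band_spec"`.
#' @export
band_spec <- function(f_min, f_max, points_per_decade = 10) {
  f_min <- as.numeric(f_min)[1L]; f_max <- as.numeric(f_max)[1L]
  if (!is.finite(f_min) || !is.finite(f_max) || f_min <= 0 ||
      f_min >= f_max)
    stop("band requires 0 < f_min < f_max", call. = FALSE)
  if (points_per_decade < 1)
    stop("points_per_decade must be >= 1", call. = FALSE)
  structure(list(f_min = f_min, f_max = f_max,
                 points_per_decade = as.integer(points_per_decade),
                 spacing = "log"),
            class = "band_spec")
}

#' @rdname band_spec
#' @param name preset name, `"tdr"` or `"thz"`.
#' @export
band_preset <- function(name = c("tdr", "thz"),
                        points_per_decade = 10) {
  name <- match.arg(name)
  switch(name,
         tdr = band_spec(5e8, 25e9, points_per_decade),
         thz = band_spec(3e11, 2.5e12, points_per_decade))
}

#' Log-spaced frequency grid for a band
#'
#' Strictly increasing log-spaced grid including both endpoints, with
#' \eqn{\lceil p \log_{10}(f_{max}/f_{min}) \rceil + 1} points for
#' `points_per_decade` \eqn{= p}.
#'
#' @param band a [band_spec].
#' @return numeric vector of frequencies in Hz.
#' @examples
#' length(make_grid(band_preset("tdr")))  # 18 points across 1.7 decades
#' @export
make_grid <- function(band) {
  stopifnot(inherits(band, "band_spec"))
  decades <- log10(band$f_max / band$f_min)
  n <- ceiling(band$points_per_decade * decades) + 1
  10^seq(log10(band$f_min), log10(band$f_max), length.out = n)
}

#' Measurement noise specification
#'
#' Multiplicative Gaussian amplitude noise applied independently to the
#' dielectric constant and loss channels, emulating the net few-percent
#' relative accuracy of broadband permittivity measurements. The default
#' level, 3%, matches the accuracy typical of averaged TDR waveform
#' measurements.
#'
#' @param relative_sigma relative standard deviation (default 0.03).
#' @param seed integer seed for reproducibility.
#' @param per_channel_independent if `TRUE` (default) the two channels draw
#'   independent noise; otherwise they share one draw per frequency.
#' @return object of class `"noise_spec"`.
#' @export
noise_spec <- function(relative_sigma = 0.03, seed = 1,
                       per_channel_independent = TRUE) {
  if (relative_sigma < 0)
    stop("relative_sigma must be >= 0", call. = FALSE)
  structure(list(relative_sigma = relative_sigma,
                 seed = as.integer(seed),
                 per_channel_independent = isTRUE(per_channel_independent),
                 rng = "Mersenne-Twister"),
            class = "noise_spec")
}

#' Simulate a noisy permittivity spectrum from a relaxation model
#'
#' Evaluates the forward model on the band grid and multiplies each channel
#' pointwise by \eqn{1 + N(0, \sigma_{rel})} factors (truncated so the loss
#' stays non-negative). With `relative_sigma = 0` the output is identical
#' to [evaluate_model()]. Deterministic given the seed in `noise`; the RNG
#' (Mersenne-Twister) is used locally without disturbing the session RNG
#' state.
#'
#' @param model a [relaxation_model].
#' @param band a [band_spec]; ignored if `frequency` is given.
#' @param noise a [noise_spec].
#' @param frequency optional explicit frequency grid in Hz.
#' @param band_label,temperature metadata for the returned spectrum.
#' @return a [permittivity_spectrum].
#' @export
simulate_spectrum <- function(model, band = band_preset("tdr"),
                              noise = noise_spec(), frequency = NULL,
                              band_label = NULL, temperature = 293) {
  stopifnot(inherits(model, "relaxation_model"),
            inherits(noise, "noise_spec"))
  if (is.null(frequency)) {
    stopifnot(inherits(band, "band_spec"))
    frequency <- make_grid(band)
  }
  if (is.null(band_label))
    band_label <- sprintf("synthetic %.3g-%.3g Hz", min(frequency),
                          max(frequency))
  clean <- evaluate_model(model, frequency, band_label = band_label,
                          temperature = temperature)
  if (noise$relative_sigma == 0) return(clean)
  n <- length(frequency)
  factors <- .with_seed(noise$seed, {
    f1 <- 1 + stats::rnorm(n, 0, noise$relative_sigma)
    f2 <- if (noise$per_channel_independent)
      1 + stats::rnorm(n, 0, noise$relative_sigma) else f1
    list(f1, f2)
  })
  permittivity_spectrum(frequency,
                        clean$eps_real * factors[[1L]],
                        pmax(clean$eps_imag * factors[[2L]], 0),
                        band_label = band_label,
                        temperature = temperature)
}

#' Built-in relaxation-model fixtures
#'
#' Parameter sets standing in for measured samples, for use in simulation
#' and recovery benchmarks.
#'
#' \describe{
#'   \item{`water_293K`}{Pure water at 293 K: a single Debye process with
#'     \eqn{\varepsilon_s \approx 80.2}, \eqn{\tau \approx 9.4} ps,
#'     \eqn{\varepsilon_\infty = 5.3}. Literature-style constants.}
#'   \item{`glycine_solution`}{3 mol% aqueous glycine: three Debye
#'     processes. The slow L process carries the reported fitted values
#'     (\eqn{\tau_L = 72} ps, L-process high-frequency limit 91.3, static
#'     permittivity 120, hence \eqn{\Delta\varepsilon_L = 28.7}); the M and
#'     H process parameters are plausible invented stand-ins (the M process
#'     is small and unpublished; H is water-like).}
#'   \item{`collagen_glycine_solution`}{4 wt% collagen + 3 mol% glycine:
#'     identical L process to `glycine_solution` — encoding the finding
#'     that the solute rotational time is unchanged by the collagen
#'     network — with slightly reduced strengths elsewhere.}
#' }
#'
#' @param name fixture name.
#' @return a [relaxation_model].
#' @examples
#' static_permittivity(fixture_model("glycine_solution"))  # 120
#' @export
fixture_model <- function(name = c("water_293K", "glycine_solution",
                                   "collagen_glycine_solution")) {
  name <- match.arg(name)
  switch(name,
    water_293K = relaxation_model(
      5.3, list(debye_process(74.9, 9.4e-12, "H"))),
    glycine_solution = relaxation_model(
      5.3, list(
        debye_process(28.7, 72e-12, "L"),     # reported L-process values
        debye_process(4.0, 25e-12, "M"),      # invented: small M process
        debye_process(82.0, 9.8e-12, "H"))),  # invented: water-like H
    collagen_glycine_solution = relaxation_model(
      5.3, list(
        debye_process(28.7, 72e-12, "L"),     # L unchanged by collagen
        debye_process(4.0, 25e-12, "M"),
        debye_process(79.0, 9.8e-12, "H"))))
}
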