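#' Single dipolar relaxation process
#'
#' One term of a superposed-relaxation dielectric function: a Debye process
#' \eqn{\Delta\varepsilon/(1 + i\omega\tau)} or, with `alpha > 0`, its
#' symmetrically broadened Cole-Cole generalisation
#' \eqn{\Delta\varepsilon/(1 + (i\omega\tau)^{1-\alpha})}.
#'
#' @param delta_eps relaxation strength \eqn{\Delta\varepsilon > 0}, the drop
#'   in \eqn{\varepsilon'} across the process.
#' @param tau relaxation time in seconds, \eqn{\tau > 0}.
#' @param label process label; conventionally `"L"`, `"M"`, `"H"` for the
#'   low-, intermediate- and high-frequency processes.
#' @param alpha Cole-Cole broadening exponent in \[0, 1); `0` (default) is a
#'   pure Debye process.
#' @return object of class `"debye_process"`.
#' @export
debye_process <- function(delta_eps, tau, label = "", alpha = 0) {
  delta_eps <- as.numeric(delta_eps)[1L]
  tau <- as.numeric(tau)[1L]
  alpha <- as.numeric(alpha)[1L]
  if (!is.finite(delta_eps) || delta_eps <= 0)
    stop("delta_eps must be finite and > 0", call. = FALSE)
  if (!is.finite(tau) || tau <= 0)
    stop("tau must be finite and > 0 (seconds)", call. = FALSE)
  if (alpha < 0 || alpha >= 1)
    stop("alpha must lie in [0, 1)", call. = FALSE)
  structure(list(delta_eps = delta_eps, tau = tau,
                 label = as.character(label)[1L], alpha = alpha),
            class = "debye_process")
}

#' Complex contribution of one relaxation process
#'
#' Evaluates \eqn{\Delta\varepsilon/(1 + (i\omega\tau)^{1-\alpha})} with
#' \eqn{\omega = 2\pi f}. At \eqn{f = 0} this is exactly
#' \eqn{\Delta\varepsilon}. The imaginary part is non-positive (loss
#' convention \eqn{\varepsilon^* = \varepsilon' - i\varepsilon''}).
#'
#' @param process a [debye_process].
#' @param frequency numeric vector of frequencies in Hz, \eqn{\ge 0}.
#' @return complex vector of the same length as `frequency`.
#' @examples
#' p <- debye_process(28.7, 72e-12, "L")
#' debye_term(p, 1 / (2 * pi * 72e-12))  # 14.35 - 14.35i at the loss peak
#' @export
debye_term <- function(process, frequency) {
  stopifnot(inherits(process, "debye_process"))
  frequency <- as.numeric(frequency)
  if (any(frequency < 0))
    stop("frequency must be non-negative", call. = FALSE)
  x <- 2 * pi * frequency * process$tau
  if (process$alpha == 0) {
    process$delta_eps / complex(real = 1, imaginary = x)
  } else {
    process$delta_eps / (1 + (complex(real = 0, imaginary = 1) * x)^(1 - process$alpha))
  }
}

#' Superposed-relaxation dielectric model
#'
#' A high-frequency limit \eqn{\varepsilon_\infty} plus a set of relaxation
#' processes, with an optional dc-conductivity term contributing
#' \eqn{\sigma_{dc}/(2\pi f \varepsilon_0)} to the loss channel only.
#' Processes are stored sorted by descending relaxation time, so the slowest
#' (lowest-frequency) process comes first.
#'
#' @param eps_inf high-frequency limiting permittivity, \eqn{\ge 1}.
#' @param processes list of [debye_process] objects (may be empty).
#' @param sigma_dc dc conductivity in S/m, \eqn{\ge 0}; default 0.
#' @return object of class `"relaxation_model"`.
#' @examples
#' water <- relaxation_model(5.3, list(debye_process(74.9, 9.4e-12, "H")))
#' static_permittivity(water)
#' @export
relaxation_model <- function(eps_inf, processes = list(), sigma_dc = 0) {
  eps_inf <- as.numeric(eps_inf)[1L]
  sigma_dc <- as.numeric(sigma_dc)[1L]
  if (!is.finite(eps_inf) || eps_inf < 1)
    stop("eps_inf must be finite and >= 1", call. = FALSE)
  if (!is.finite(sigma_dc) || sigma_dc < 0)
    stop("sigma_dc must be finite and >= 0 (S/m)", call. = FALSE)
  if (inherits(processes, "debye_process")) processes <- list(processes)
  if (!all(vapply(processes, inherits, logical(1), "debye_process")))
    stop("processes must be a list of debye_process objects", call. = FALSE)
  if (length(processes)) {
    taus <- vapply(processes, `[[`, numeric(1), "tau")
    processes <- processes[order(taus, decreasing = TRUE)]
    labels <- vapply(processes, `[[`, character(1), "label")
    if (anyDuplicated(labels[nzchar(labels)]))
      stop("process labels must be unique", call. = FALSE)
  }
  structure(list(eps_inf = eps_inf, processes = processes,
                 sigma_dc = sigma_dc),
            class = "relaxation_model")
}

#' @export
print.relaxation_model <- function(x, ...) {
  cat(sprintf("Relaxation model: eps_inf = %.4g, %d process(es)",
              x$eps_inf, length(x$processes)))
  if (x$sigma_dc > 0) cat(sprintf(", sigma_dc = %.3g S/m", x$sigma_dc))
  cat("\n")
  for (p in x$processes)
    cat(sprintf("  %-2s delta_eps = %8.4g  tau = %8.4g ps%s\n",
                ifelse(nzchar(p$label), p$label, "-"),
                p$delta_eps, p$tau * 1e12,
                if (p$alpha > 0) sprintf("  (Cole-Cole alpha = %.3g)", p$alpha)
                else ""))
  cat(sprintf("  static permittivity eps_s = %.4g\n",
              static_permittivity(x)))
  invisible(x)
}

#' Static permittivity of a relaxation model
#'
#' \eqn{\varepsilon_s = \varepsilon_\infty + \sum_k \Delta\varepsilon_k}, the
#' zero-frequency limit of the dielectric constant.
#'
#' @param model a [relaxation_model].
#' @return numeric scalar \eqn{\ge \varepsilon_\infty}.
#' @export
static_permittivity <- function(model) {
  stopifnot(inherits(model, "relaxation_model"))
  model$eps_inf +
    sum(vapply(model$processes, `[[`, numeric(1), "delta_eps"))
}

#' Evaluate a relaxation model on a frequency grid
#'
#' Forward model: \eqn{\varepsilon'(f) = \varepsilon_\infty + \sum_k
#' \mathrm{Re}[t_k(f)]} and \eqn{\varepsilon''(f) = \sum_k
#' |\mathrm{Im}[t_k(f)]| + \sigma_{dc}/(2\pi f\varepsilon_0)}, where
#' \eqn{t_k} are the process terms of [debye_term()].
#'
#' @param model a [relaxation_model].
#' @param frequency numeric vector of frequencies in Hz; must be strictly
#'   positive when `sigma_dc > 0` (the conduction loss diverges at dc).
#' @param band_label,temperature metadata for the returned spectrum.
#' @return a [permittivity_spectrum] on the given grid.
#' @export
evaluate_model <- function(model, frequency, band_label = "model",
                           temperature = 293) {
  stopifnot(inherits(model, "relaxation_model"))
  frequency <- as.numeric(frequency)
  if (model$sigma_dc > 0 && any(frequency <= 0))
    stop("frequencies must be > 0 when sigma_dc > 0", call. = FALSE)
  if (any(frequency < 0))
    stop("frequency must be non-negative", call. = FALSE)
  er <- rep(model$eps_inf, length(frequency))
  ei <- numeric(length(frequency))
  for (p in model$processes) {
    term <- debye_term(p, frequency)
    er <- er + Re(term)
    ei <- ei + abs(Im(term))
  }
  if (model$sigma_dc > 0)
    ei <- ei + model$sigma_dc / (2 * pi * frequency * .eps0)
  permittivity_spectrum(frequency, er, ei, band_label = band_label,
                        temperature = temperature)
}
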