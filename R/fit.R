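#' Fitting configuration
#'
#' Bundles the tunables of [fit_relaxation()] so that several candidate
#' configurations can be compared with [compare_models()].
#'
#' @param n_processes number of relaxation processes to fit (1-4).
#' @param weight_mode `"relative"` (default; each residual divided by the
#'   channel's data magnitude, floored at 1 -- appropriate when both channels
#'   carry the same relative accuracy) or `"uniform"`.
#' @param conductivity `"off"` (default), `"on"` (always co-fit a dc
#'   conductivity loss term), or `"auto"` (co-fit it only when the
#'   lowest-frequency loss exceeds the fitted relaxation-only loss by more
#'   than 10 percent, the signature of ionic conduction).
#' @param tau_bounds optional 2-column matrix (one row per process, seconds)
#'   of box constraints on the relaxation times, rows ordered slow to fast.
#'   Default: the data band padded by three decades either side.
#' @param max_iterations Levenberg-Marquardt iteration cap.
#' @param tolerance relative convergence tolerance on the residual and the
#'   parameters.
#' @param n_starts number of multi-start repeats: start 1 is the
#'   deterministic [initial_guess()]; the rest perturb it log-normally to
#'   guard against local minima.
#' @param seed integer seed for the multi-start perturbations.
#' @return object of class `"fit_config"` (a named list).
#' @export
fit_config <- function(n_processes = 3, weight_mode = c("relative", "uniform"),
                       conductivity = c("off", "on", "auto"),
                       tau_bounds = NULL, max_iterations = 200,
                       tolerance = 1e-10, n_starts = 5, seed = 1) {
  weight_mode <- match.arg(weight_mode)
  conductivity <- match.arg(conductivity)
  n_processes <- as.integer(n_processes)
  if (n_processes < 1L || n_processes > 4L)
    stop("n_processes must be between 1 and 4", call. = FALSE)
  if (!is.null(tau_bounds)) {
    tau_bounds <- as.matrix(tau_bounds)
    if (ncol(tau_bounds) != 2L || nrow(tau_bounds) != n_processes)
      stop("tau_bounds must be an n_processes x 2 matrix", call. = FALSE)
    if (any(tau_bounds <= 0) || any(tau_bounds[, 1] >= tau_bounds[, 2]))
      stop("tau_bounds must be positive intervals (lower < upper)",
           call. = FALSE)
  }
  structure(list(n_processes = n_processes, weight_mode = weight_mode,
                 conductivity = conductivity, tau_bounds = tau_bounds,
                 max_iterations = as.integer(max_iterations),
                 tolerance = tolerance, n_starts = as.integer(n_starts),
                 seed = as.integer(seed)),
            class = "fit_config")
}

## Process labels by descending tau: slowest is L, then M, H, P4.
.process_labels <- function(n) c("L", "M", "H", "P4")[seq_len(n)]

#' Initial parameter guess for a multi-Debye fit
#'
#' Seeds the relaxation times log-spaced across the reciprocal data band
#' \eqn{[1/(2\pi f_{max}),\, 1/(2\pi f_{min})]}, splits the observed span of
#' \eqn{\varepsilon'} equally among the process strengths, and seeds
#' \eqn{\varepsilon_\infty} from the highest-frequency \eqn{\varepsilon'}.
#'
#' @param spectrum a [permittivity_spectrum] spanning at least one decade.
#' @param n_processes number of processes (1-4).
#' @return a [relaxation_model] usable as a starting point.
#' @export
initial_guess <- function(spectrum, n_processes = 3) {
  stopifnot(inherits(spectrum, "permittivity_spectrum"))
  n_processes <- as.integer(n_processes)
  if (n_processes < 1L || n_processes > 4L)
    stop("n_processes must be between 1 and 4", call. = FALSE)
  f <- spectrum$frequency
  if (max(f) / min(f) < 10)
    stop("spectrum must span at least one decade of frequency",
         call. = FALSE)
  if (all(spectrum$eps_imag == 0))
    stop("degenerate spectrum: loss is zero everywhere, nothing to fit",
         call. = FALSE)
  tau_fast <- 1 / (2 * pi * max(f))
  tau_slow <- 1 / (2 * pi * min(f))
  taus <- if (n_processes == 1L) sqrt(tau_fast * tau_slow) else
    exp(seq(log(tau_slow), log(tau_fast), length.out = n_processes))
  span <- max(spectrum$eps_real) - min(spectrum$eps_real)
  deps <- max(span / n_processes, 1e-3)
  eps_inf <- max(spectrum$eps_real[which.max(f)], 1.001)
  labs <- .process_labels(n_processes)
  procs <- lapply(seq_len(n_processes), function(k)
    debye_process(deps, taus[k], labs[k]))
  relaxation_model(eps_inf, procs)
}

## Pack/unpack: all positive parameters are optimised on the log scale so
## positivity is structural, not clipped.
.pack <- function(model, with_sigma) {
  par <- c(log(model$eps_inf - 1),
           unlist(lapply(model$processes, function(p)
     c(log(p$delta_eps), log(p$tau)))))
  if (with_sigma)
    par <- c(par, log(max(model$sigma_dc, 1e-6)))
  par
}

## Builds the model without constructor validation: during optimisation the
## solver may probe extreme parameters, so exponents are clamped to keep
## every value finite. Validated relaxation_model objects are rebuilt from
## the final parameters only.
.unpack <- function(par, n_processes, with_sigma) {
  par <- pmin(pmax(par, -500), 500)
  procs <- vector("list", n_processes)
  for (k in seq_len(n_processes)) {
    i <- 2L * (k - 1L) + 2L
    procs[[k]] <- structure(list(delta_eps = exp(par[i]),
                                 tau = exp(par[i + 1L]),
                                 label = "", alpha = 0),
                            class = "debye_process")
  }
  taus <- vapply(procs, `[[`, numeric(1), "tau")
  structure(list(eps_inf = 1 + exp(par[1L]),
                 processes = procs[order(taus, decreasing = TRUE)],
                 sigma_dc = if (with_sigma) exp(par[length(par)]) else 0),
            class = "relaxation_model")
}

.fit_residuals <- function(par, spectrum, n_processes, with_sigma, w_real,
                           w_imag) {
  m <- .unpack(par, n_processes, with_sigma)
  sp <- evaluate_model(m, spectrum$frequency)
  c((spectrum$eps_real - sp$eps_real) / w_real,
    (spectrum$eps_imag - sp$eps_imag) / w_imag)
}

## Run code under a temporary RNG state.
.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Fit a superposed-Debye relaxation model to a permittivity spectrum
#'
#' Decomposes a spectrum into \eqn{\varepsilon_\infty} plus `n_processes`
#' Debye relaxation terms (optionally plus a dc-conductivity loss term) by
#' Levenberg-Marquardt least squares on the joint
#' \eqn{(\varepsilon', \varepsilon'')} residual. Strengths and times are
#' optimised on the log scale, so the fitted \eqn{\Delta\varepsilon} and
#' \eqn{\tau} are strictly positive by construction. After fitting,
#' processes are relabelled by descending \eqn{\tau}: the slowest is `L`,
#' then `M`, `H`.
#'
#' @param spectrum a [permittivity_spectrum]; must contain at least twice as
#'   many points as free parameters.
#' @param n_processes number of Debye processes (1-4); ignored if `config`
#'   is supplied.
#' @param ... further arguments passed to [fit_config()].
#' @param config a [fit_config]; overrides `n_processes` and `...`.
#' @param start optional [relaxation_model] used as the starting point
#'   instead of [initial_guess()] (e.g. to refit from a previous solution).
#' @return An object of class `"dielax_fit"` with components `model` (the
#'   fitted [relaxation_model]), `std_errors` (delta-method standard errors
#'   on the natural scale), `residual_rms_real`, `residual_rms_imag`
#'   (unweighted per-channel RMS), `ssr` (weighted sum of squares),
#'   `n_iterations`, `converged`, `spectrum`, `config`. Methods: `print`,
#'   `summary`, `coef`, `predict`, `residuals`, `fitted`, `plot`,
#'   `simulate`.
#' @examples
#' truth <- fixture_model("water_293K")
#' sp <- simulate_spectrum(truth, band_spec(5e8, 25e9), noise_spec(0))
#' fit <- fit_relaxation(sp, n_processes = 1)
#' coef(fit)
#' @export
fit_relaxation <- function(spectrum, n_processes = 3, ..., config = NULL,
                           start = NULL) {
  stopifnot(inherits(spectrum, "permittivity_spectrum"))
  if (is.null(config))
    config <- fit_config(n_processes = n_processes, ...)
  stopifnot(inherits(config, "fit_config"))

  fit1 <- .fit_once(spectrum, config, with_sigma = (config$conductivity == "on"),
                    start = start)
  if (config$conductivity == "auto" && !.has_dc_excess(spectrum, fit1$model))
    return(fit1)
  if (config$conductivity != "auto")
    return(fit1)
  ## auto + excess detected: co-fit sigma_dc, keep whichever explains the
  ## data better per parameter (same penalised criterion as compare_models)
  fit2 <- .fit_once(spectrum, config, with_sigma = TRUE, start = start)
  if (.fit_criterion(fit2) < .fit_criterion(fit1)) fit2 else fit1
}

## dc-conductivity heuristic: loss at the lowest frequency exceeds the
## relaxation-only fitted loss there by > 5%. Deliberately permissive -- a
## relaxation-only fit partially absorbs a conduction tail, so the residual
## excess understates the contamination; a false trigger only costs a trial
## fit that the penalised criterion then rejects.
.has_dc_excess <- function(spectrum, model) {
  m <- evaluate_model(relaxation_model(model$eps_inf, model$processes),
                      spectrum$frequency[1L])
  spectrum$eps_imag[1L] > 1.05 * m$eps_imag[1L]
}

.fit_once <- function(spectrum, config, with_sigma, start = NULL) {
  n <- length(spectrum$frequency)
  n_par <- 1L + 2L * config$n_processes + as.integer(with_sigma)
  if (n < 2L * n_par)
    stop("spectrum too short: need at least ", 2L * n_par,
         " points for ", n_par, " free parameters", call. = FALSE)

  if (config$weight_mode == "relative") {
    w_real <- pmax(abs(spectrum$eps_real), 1)
    w_imag <- pmax(abs(spectrum$eps_imag), 1)
  } else {
    w_real <- w_imag <- rep(1, n)
  }

  guess <- if (is.null(start)) initial_guess(spectrum, config$n_processes)
           else start
  if (length(guess$processes) != config$n_processes)
    stop("start model must have n_processes processes", call. = FALSE)
  if (with_sigma && guess$sigma_dc == 0)
    ## seed the conductivity as if half the lowest-frequency loss were
    ## ionic conduction; the optimiser shrinks it freely on the log scale
    guess$sigma_dc <- pi * spectrum$frequency[1L] * .eps0 *
      spectrum$eps_imag[1L]
  par0 <- .pack(guess, with_sigma)

  ## box constraints on log(tau); other parameters unconstrained
  lower <- rep(-Inf, n_par); upper <- rep(Inf, n_par)
  tb <- config$tau_bounds
  if (is.null(tb)) {
    f <- spectrum$frequency
    tb <- matrix(rep(c(1 / (2 * pi * max(f)) / 1e3,
                       1 / (2 * pi * min(f)) * 1e3),
                     each = config$n_processes), ncol = 2)
  }
  tb <- tb[order(-tb[, 1]), , drop = FALSE]  # slow-to-fast, matching labels
  for (k in seq_len(config$n_processes)) {
    i <- 2L * (k - 1L) + 3L
    lower[i] <- log(tb[k, 1]); upper[i] <- log(tb[k, 2])
  }
  par0 <- pmin(pmax(par0, lower), upper)

  starts <- list(par0)
  if (config$n_starts > 1L) {
    perturbed <- .with_seed(config$seed, lapply(seq_len(config$n_starts - 1L),
      function(j) pmin(pmax(par0 + stats::rnorm(n_par, 0, 0.5), lower), upper)))
    starts <- c(starts, perturbed)
  }

  best <- NULL
  for (p0 in starts) {
    res <- tryCatch(
      minpack.lm::nls.lm(
        par = p0, lower = lower, upper = upper,
        fn = .fit_residuals, spectrum = spectrum,
        n_processes = config$n_processes, with_sigma = with_sigma,
        w_real = w_real, w_imag = w_imag,
        control = minpack.lm::nls.lm.control(
          maxiter = config$max_iterations,
          ftol = config$tolerance, ptol = config$tolerance)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$deviance < best$deviance) best <- res
  }
  if (is.null(best))
    stop("all optimisation starts failed", call. = FALSE)

  model <- .unpack(best$par, config$n_processes, with_sigma)
  labs <- .process_labels(length(model$processes))
  for (k in seq_along(model$processes))  # already sorted by descending tau
    model$processes[[k]]$label <- labs[k]

  converged <- best$info %in% 1:4
  fitted_sp <- evaluate_model(model, spectrum$frequency)
  r_re <- spectrum$eps_real - fitted_sp$eps_real
  r_im <- spectrum$eps_imag - fitted_sp$eps_imag

  ## delta-method standard errors on the natural scale from the local
  ## curvature of the weighted least-squares problem
  se_nat <- rep(NA_real_, n_par)
  dof <- 2L * n - n_par
  cov_log <- tryCatch({
    s2 <- best$deviance / max(dof, 1L)
    s2 * solve(best$hessian)
  }, error = function(e) NULL)
  if (!is.null(cov_log)) {
    se_log <- sqrt(pmax(diag(cov_log), 0))
    se_nat <- se_log * exp(best$par)  # delta method; d(1+e^u)/du = e^u
  }
  ## permute parameter blocks into descending-tau order to match the
  ## relabelled processes
  k <- seq_len(config$n_processes)
  tau_order <- order(exp(best$par[2L * k + 1L]), decreasing = TRUE)
  perm <- c(1L, as.vector(rbind(2L * tau_order, 2L * tau_order + 1L)))
  if (with_sigma) perm <- c(perm, n_par)
  se_nat <- se_nat[perm]
  names(se_nat) <- .par_names(config$n_processes, with_sigma)

  structure(list(model = model,
                 std_errors = se_nat,
                 residual_rms_real = sqrt(mean(r_re^2)),
                 residual_rms_imag = sqrt(mean(r_im^2)),
                 ssr = best$deviance,
                 n_par = n_par,
                 n_iterations = best$niter,
                 converged = converged,
                 spectrum = spectrum,
                 config = config),
            class = "dielax_fit")
}

.par_names <- function(n_processes, with_sigma) {
  labs <- .process_labels(n_processes)
  nm <- c("eps_inf", as.vector(rbind(paste0("delta_eps_", labs),
                                     paste0("tau_", labs))))
  if (with_sigma) nm <- c(nm, "sigma_dc")
  nm
}

## Penalised-residual model-selection criterion: Gaussian AIC on the
## weighted residuals, 2N log-likelihood up to a constant plus 2p.
.fit_criterion <- function(fit) {
  n_resid <- 2L * length(fit$spectrum$frequency)
  n_resid * log(fit$ssr / n_resid) + 2 * fit$n_par
}

#' @export
coef.dielax_fit <- function(object, ...) {
  m <- object$model
  out <- c(eps_inf = m$eps_inf)
  for (p in m$processes) {
    out[paste0("delta_eps_", p$label)] <- p$delta_eps
    out[paste0("tau_", p$label)] <- p$tau
  }
  if (m$sigma_dc > 0) out["sigma_dc"] <- m$sigma_dc
  out
}

#' @export
fitted.dielax_fit <- function(object, ...) {
  evaluate_model(object$model, object$spectrum$frequency,
                 band_label = "fitted")
}

#' @rdname fit_relaxation
#' @param object,x a fitted `"dielax_fit"` object.
#' @export
residuals.dielax_fit <- function(object, ...) {
  f <- fitted(object)
  cbind(eps_real = object$spectrum$eps_real - f$eps_real,
        eps_imag = object$spectrum$eps_imag - f$eps_imag)
}

#' @rdname fit_relaxation
#' @param frequency frequencies (Hz) at which to evaluate the fitted model;
#'   defaults to the data grid.
#' @export
predict.dielax_fit <- function(object, frequency = NULL, ...) {
  if (is.null(frequency)) frequency <- object$spectrum$frequency
  evaluate_model(object$model, frequency, band_label = "predicted")
}

#' @rdname fit_relaxation
#' @param nsim number of spectra to simulate from the fitted model.
#' @param seed integer seed.
#' @param relative_sigma relative noise level for [simulate_spectrum()].
#' @export
simulate.dielax_fit <- function(object, nsim = 1, seed = 1,
                                relative_sigma = 0.03, ...) {
  band <- band_spec(min(object$spectrum$frequency),
                    max(object$spectrum$frequency))
  lapply(seq_len(nsim), function(i)
    simulate_spectrum(object$model, band,
                      noise_spec(relative_sigma, seed = seed + i - 1L),
                      frequency = object$spectrum$frequency))
}

#' @export
print.dielax_fit <- function(x, ...) {
  cat(sprintf("Multi-Debye relaxation fit (%d process%s%s), %s\n",
              length(x$model$processes),
              if (length(x$model$processes) == 1L) "" else "es",
              if (x$model$sigma_dc > 0) " + dc conductivity" else "",
              if (x$converged) "converged" else "NOT converged"))
  print(x$model)
  cat(sprintf("  residual RMS: eps' %.3g, eps'' %.3g  (%d iterations)\n",
              x$residual_rms_real, x$residual_rms_imag, x$n_iterations))
  invisible(x)
}

#' @export
summary.dielax_fit <- function(object, ...) {
  est <- coef(object)
  se <- object$std_errors[names(object$std_errors) %in% names(est)]
  tab <- data.frame(estimate = est,
                    std_error = se[names(est)],
                    row.names = names(est))
  structure(list(table = tab, fit = object), class = "summary.dielax_fit")
}

#' @export
print.summary.dielax_fit <- function(x, ...) {
  print(x$fit)
  cat("\nParameter estimates (tau in seconds):\n")
  print(signif(x$table, 5))
  invisible(x)
}

#' @rdname fit_relaxation
#' @param ... unused.
#' @export
plot.dielax_fit <- function(x, ...) {
  sp <- x$spectrum
  grid <- exp(seq(log(min(sp$frequency)), log(max(sp$frequency)),
                  length.out = 200))
  m <- evaluate_model(x$model, grid)
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(sp$frequency, sp$eps_real, log = "x",
                 xlab = "frequency (Hz)", ylab = "dielectric constant")
  graphics::lines(grid, m$eps_real, col = 2)
  graphics::plot(sp$frequency, sp$eps_imag, log = "x",
                 xlab = "frequency (Hz)", ylab = "dielectric loss")
  graphics::lines(grid, m$eps_imag, col = 2)
  invisible(x)
}

#' Compare relaxation-model fits of differing complexity
#'
#' Fits the same spectrum under each supplied configuration and ranks the
#' converged fits by a penalised-residual criterion (Gaussian AIC on the
#' weighted residuals: \eqn{2N\log(\mathrm{SSR}/2N) + 2p}), so extra
#' processes must earn their keep. Non-converged fits are reported but
#' excluded from the ranking.
#'
#' @param spectrum a [permittivity_spectrum].
#' @param configs list of [fit_config] objects (length \eqn{\ge} 2).
#' @return object of class `"dielax_model_comparison"`: list with `fits`
#'   (in input order), `criterion` (per fit; `NA` when not converged) and
#'   `ranking` (indices of converged fits, best first).
#' @export
compare_models <- function(spectrum, configs) {
  if (length(configs) < 2L)
    stop("need at least two configurations to compare", call. = FALSE)
  stopifnot(all(vapply(configs, inherits, logical(1), "fit_config")))
  fits <- lapply(configs, function(cfg)
    fit_relaxation(spectrum, config = cfg))
  crit <- vapply(fits, function(f)
    if (f$converged) .fit_criterion(f) else NA_real_, numeric(1))
  ranking <- order(crit)[seq_len(sum(!is.na(crit)))]
  structure(list(fits = fits, criterion = crit, ranking = ranking),
            class = "dielax_model_comparison")
}

#' @export
print.dielax_model_comparison <- function(x, ...) {
  cat("Model comparison (penalised residual criterion, lower is better):\n")
  for (i in seq_along(x$fits)) {
    f <- x$fits[[i]]
    cat(sprintf("  [%d] %d process(es)%s: criterion %s%s\n", i,
                length(f$model$processes),
                if (f$model$sigma_dc > 0) " + dc" else "",
                if (is.na(x$criterion[i])) "--" else
                  sprintf("%.2f", x$criterion[i]),
                if (is.na(x$criterion[i])) " (not converged)" else
                  if (i == x$ranking[1L]) "  <- best" else ""))
  }
  invisible(x)
}
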