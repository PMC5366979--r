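#' Serialize a relaxation fit to JSON
#'
#' Writes all model parameters in SI units (relaxation times in seconds,
#' conductivity in S/m) plus a picosecond convenience field per process,
#' together with the fit diagnostics. `read_report()` restores the model
#' and diagnostics to full double precision.
#'
#' @param fit a `"dielax_fit"` object from [fit_relaxation()], or a bare
#'   [relaxation_model] (diagnostics are then omitted).
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_report <- function(fit, path) {
  if (inherits(fit, "relaxation_model")) {
    model <- fit
    diag <- NULL
  } else if (inherits(fit, "dielax_fit")) {
    model <- fit$model
    diag <- list(residual_rms_real = fit$residual_rms_real,
                 residual_rms_imag = fit$residual_rms_imag,
                 ssr = fit$ssr,
                 n_iterations = fit$n_iterations,
                 converged = fit$converged,
                 std_errors = as.list(fit$std_errors))
  } else stop("fit must be a dielax_fit or relaxation_model", call. = FALSE)

  procs <- lapply(model$processes, function(p)
    list(label = p$label, delta_eps = p$delta_eps,
         tau_s = p$tau, tau_ps = p$tau * 1e12, alpha = p$alpha))
  obj <- list(model = list(eps_inf = model$eps_inf,
                           sigma_dc = model$sigma_dc,
                           static_permittivity = static_permittivity(model),
                           processes = procs))
  if (!is.null(diag)) obj$diagnostics <- diag
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_report
#' @return `read_report()`: a list with `model` (a [relaxation_model]) and
#'   `diagnostics` (list or `NULL`).
#' @export
read_report <- function(path) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(obj$model))
    stop("not a relaxation fit report: ", path, call. = FALSE)
  procs <- lapply(obj$model$processes, function(p)
    debye_process(p$delta_eps, p$tau_s, label = p$label,
                  alpha = if (is.null(p$alpha)) 0 else p$alpha))
  model <- relaxation_model(obj$model$eps_inf, procs,
                            sigma_dc = obj$model$sigma_dc)
  diag <- obj$diagnostics
  if (!is.null(diag))
    diag$std_errors <- unlist(diag$std_errors)
  list(model = model, diagnostics = diag)
}
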