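#' Complex permittivity spectrum
#'
#' Container for a sampled complex permittivity \eqn{\varepsilon^*(f) =
#' \varepsilon' - i\varepsilon''} versus frequency. The loss
#' \eqn{\varepsilon''} is stored as a non-negative magnitude; the complex
#' value is formed internally where needed. Frequencies are in Hz at every
#' interface; the angular frequency \eqn{\omega = 2\pi f} is computed
#' internally.
#'
#' @param frequency numeric vector of frequencies in Hz, strictly positive.
#'   Need not be sorted; the constructor sorts ascending.
#' @param eps_real numeric vector, dielectric constant \eqn{\varepsilon'}.
#' @param eps_imag numeric vector, dielectric loss \eqn{\varepsilon''}
#'   (non-negative).
#' @param band_label free-text band annotation, e.g. `"TDR"` or `"THz-TDS"`.
#' @param temperature sample temperature in K.
#' @return An object of class `"permittivity_spectrum"`: a list with elements
#'   `frequency`, `eps_real`, `eps_imag`, `band_label`, `temperature`.
#' @examples
#' sp <- permittivity_spectrum(c(1e9, 2e9, 3e9), c(75, 70, 64), c(10, 18, 24))
#' sp
#' @export
permittivity_spectrum <- function(frequency, eps_real, eps_imag,
                                  band_label = "", temperature = 293) {
  frequency <- as.numeric(frequency)
  eps_real <- as.numeric(eps_real)
  eps_imag <- as.numeric(eps_imag)
  n <- length(frequency)
  if (n < 1L)
    stop("spectrum must contain at least one point", call. = FALSE)
  if (length(eps_real) != n || length(eps_imag) != n)
    stop("frequency, eps_real and eps_imag must have equal length",
         call. = FALSE)
  if (anyNA(frequency) || anyNA(eps_real) || anyNA(eps_imag))
    stop("spectrum values must be non-missing and numeric", call. = FALSE)
  if (any(frequency <= 0))
    stop("frequencies must be strictly positive (Hz)", call. = FALSE)
  if (any(eps_imag < 0))
    stop("dielectric loss eps_imag must be non-negative", call. = FALSE)
  ord <- order(frequency)
  frequency <- frequency[ord]
  if (anyDuplicated(frequency))
    stop("duplicate frequencies are not allowed", call. = FALSE)
  structure(
    list(frequency = frequency,
         eps_real = eps_real[ord],
         eps_imag = eps_imag[ord],
         band_label = as.character(band_label)[1L],
         temperature = as.numeric(temperature)[1L]),
    class = "permittivity_spectrum")
}

#' @export
print.permittivity_spectrum <- function(x, ...) {
  cat(sprintf("Permittivity spectrum%s: %d points, %.3g - %.3g Hz\n",
              if (nzchar(x$band_label)) paste0(" [", x$band_label, "]") else "",
              length(x$frequency), min(x$frequency), max(x$frequency)))
  cat(sprintf("  eps' in [%.4g, %.4g], eps'' in [%.4g, %.4g], T = %g K\n",
              min(x$eps_real), max(x$eps_real),
              min(x$eps_imag), max(x$eps_imag), x$temperature))
  invisible(x)
}

#' @export
as.data.frame.permittivity_spectrum <- function(x, ...) {
  data.frame(frequency_hz = x$frequency,
             eps_real = x$eps_real,
             eps_imag = x$eps_imag)
}

#' @export
length.permittivity_spectrum <- function(x) length(x$frequency)

#' Complex permittivity values of a spectrum
#'
#' Returns \eqn{\varepsilon' - i\varepsilon''} as a complex vector.
#'
#' @param spectrum a [permittivity_spectrum].
#' @return complex vector, one value per frequency.
#' @export
complex_permittivity <- function(spectrum) {
  stopifnot(inherits(spectrum, "permittivity_spectrum"))
  complex(real = spectrum$eps_real, imaginary = -spectrum$eps_imag)
}

#' Read a permittivity spectrum from delimited text
#'
#' Reads a header-rowed delimited text file with columns for frequency (Hz),
#' dielectric constant and dielectric loss. Lines starting with `#` are
#' comments. Rows are sorted by frequency; duplicate frequencies are an error.
#'
#' @param path file path.
#' @param columns named character vector mapping the roles `frequency`,
#'   `eps_real`, `eps_imag` to column names in the file. Defaults to
#'   `frequency_hz`, `eps_real`, `eps_imag`.
#' @param sep field separator (default `","`).
#' @param band_label,temperature metadata attached to the returned spectrum.
#' @return a [permittivity_spectrum].
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("frequency_hz,eps_real,eps_imag",
#'              "1e9,75,10", "2e9,70,18"), tf)
#' read_spectrum(tf)
#' @export
read_spectrum <- function(path,
                          columns = c(frequency = "frequency_hz",
                                      eps_real = "eps_real",
                                      eps_imag = "eps_imag"),
                          sep = ",", band_label = "", temperature = 293) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  need <- c("frequency", "eps_real", "eps_imag")
  if (!all(need %in% names(columns)))
    stop("`columns` must name frequency, eps_real and eps_imag",
         call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          comment.char = "#", stringsAsFactors = FALSE)
  missing_cols <- setdiff(unname(columns[need]), names(df))
  if (length(missing_cols))
    stop("missing column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  f <- df[[columns[["frequency"]]]]
  if (!is.numeric(f))
    stop("frequency column is not numeric", call. = FALSE)
  permittivity_spectrum(f,
                        df[[columns[["eps_real"]]]],
                        df[[columns[["eps_imag"]]]],
                        band_label = band_label,
                        temperature = temperature)
}

#' Write a permittivity spectrum to delimited text
#'
#' Writes the three-column schema `frequency_hz, eps_real, eps_imag` with a
#' header row, readable back with [read_spectrum()].
#'
#' @param spectrum a [permittivity_spectrum].
#' @param path file path.
#' @param sep field separator (default `","`).
#' @return invisibly, `path`.
#' @export
write_spectrum <- function(spectrum, path, sep = ",") {
  stopifnot(inherits(spectrum, "permittivity_spectrum"))
  utils::write.table(as.data.frame(spectrum), path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
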