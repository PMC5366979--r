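# Shared builders for the test suite.

# Reference solute rows used by the Perrin worked example:
# name, observed tau_L (ps), semi-axes (Angstrom), permittivities,
# expected predicted tau_a (ps).
solute_rows <- function() {
  cbind(amino_acid_table(),
        tau_a_expected_ps = c(74, 108, 114, 282))
}

# Write a spectrum CSV and return its path.
write_spectrum_csv <- function(lines) {
  tf <- tempfile(fileext = ".csv")
  writeLines(lines, tf)
  tf
}

# A quick fit config for tests that exercise the optimiser repeatedly.
fast_fit <- function(n_processes = 3, seed = 1, n_starts = 2)
  fit_config(n_processes = n_processes, seed = seed, n_starts = n_starts)
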