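# shared fixtures: everything is built in code at test time

quick_mcmc <- function(seed = 7L, chains = 2L, warmup = 400L, draws = 400L)
  mcmc_config(chains = chains, warmup_draws = warmup,
              sampling_draws = draws, seed = seed)

# a small, valid hand-made dataset (3 series, 1 calibrated)
tiny_dataset <- function() {
  error_dataset(list(
    aggregate_series("a", 30, 0.10, 1.20),
    aggregate_series("b", 50, -0.30, 0.90, n_c = 40, m_c = -0.20,
                     s_c = 0.80),
    aggregate_series("c", 20, 0.50, 1.50)),
    provenance = "tiny test fixture")
}

# write a dataset CSV into a temp file, returning the path
temp_csv <- function(d, ...) {
  path <- tempfile(fileext = ".csv")
  write_series_table(d, path, ...)
  path
}

csv_from_text <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}
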