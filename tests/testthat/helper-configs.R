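# small configurations reused across tests

# tiny matrix config without planted structure
tiny_config <- function(seed = 1L, noise_sd = 0.3, n_genes = 40L,
                        n_hb_genes = 20L, ...) {
  sim_config(seed = seed, n_genes = n_genes, n_hb_genes = n_hb_genes,
             module_spec = list(), noise_sd = noise_sd,
             library_size_cv = 0, ...)
}

# hand-built expression matrix from a named value list (2 patients)
manual_matrix <- function(values) {
  expression_matrix(values)
}

# one unit in the last printed digit of a reported value
printed_ulp <- function(printed, sig_digits) {
  10^(floor(log10(abs(printed))) - (sig_digits - 1))
}
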