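# Small, fast study configurations used across tests.
tiny_config <- function(seed = 101, ...) {
  synth_config(n_trees = 4, n_dates = 5, n_replicate_spectra = 3,
               seed = seed, ...)
}

noise_free_config <- function(...) {
  synth_config(tree_sd = 0, psi_sd = 0, jmax_cv = 0, aci_noise_sd = 0,
               spectral_noise_sd = 0, ...)
}

# Cached default study shared by the end-to-end acceptance checks.
default_study_cache <- new.env(parent = emptyenv())
default_study_dataset <- function() {
  if (is.null(default_study_cache$data)) {
    study <- simulate_study(synth_config(seed = 1))
    default_study_cache$study <- study
    default_study_cache$data <-
      suppressMessages(study_dataset(study, "fitted"))
  }
  default_study_cache$data
}
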