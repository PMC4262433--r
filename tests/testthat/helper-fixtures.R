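# small configurations used across tests; defaults elsewhere are the
# full study-emulation settings
small_config <- function(seed = 42L, ...) {
  study_config(seed = seed, n_cells = 2000L, ...)
}

# noise-free decay data on the kinetic model, one replicate per timepoint
noiseless_decay <- function(times, b, mu, k, s0 = 1) {
  data.frame(time_h = times, replicate = 1L,
             signal = b + (s0 - b) * exp(-(mu + k) * times))
}

# minimal hand-built lipidome table
mini_lipidome <- function() {
  data.frame(
    species_label = c("52:2", "52:2", "54:3", "17:0/17:0/17:0"),
    intensity = c(300, 200, 1000, 1000),
    is_standard = c(FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
}
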