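# Small, fast synthetic configuration shared across tests (full vocabulary,
# short recordings, few animals).
tiny_config <- function(seed = 42L, ...) {
  synthetic_config(n_animals_per_context = 4L, duration_s = 240, seed = seed,
                   ...)
}

# Sequence fixture built from explicit label vectors.
seq_fixture <- function(labels_by_animal, context = "solitary") {
  dplyr::bind_rows(lapply(seq_along(labels_by_animal), function(i) {
    syllable_sequence(sprintf("%s%02d", toupper(substr(context, 1, 1)), i),
                      sprintf("A%02d", i), context, labels_by_animal[[i]])
  }))
}
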