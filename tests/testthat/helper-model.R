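# Heavy objects built once per test run and shared across files.

.sladscan_test_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .sladscan_test_cache, inherits = FALSE)) {
    assign(key, expr, envir = .sladscan_test_cache)
  }
  get(key, envir = .sladscan_test_cache, inherits = FALSE)
}

# small, fast model for unit tests of the loop plumbing
tiny_model <- function() {
  cached("tiny_model", {
    img <- generic_training_image(48L)
    pairs <- build_training_set(img, masks_per_level = 2L,
                                pairs_per_mask = 250L, seed = 4L)
    train_erd_model(pairs, epochs = 25L, seed = 11L)
  })
}

# the shipped configuration: full-size sample-agnostic model
default_model <- function() {
  cached("default_model", train_default_model(seed = 1L))
}
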