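## Memoized scaled-down training run shared by the learning-check and
## reference-sensitivity acceptance tests (trained once per test session).

.desk_cache <- new.env(parent = emptyenv())

desk_fit <- function() {
  if (is.null(.desk_cache$fit))
    .desk_cache$fit <- train_daasr(train_config("desk", seed = 1L))
  .desk_cache$fit
}
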