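# The replicated recovery study is expensive; several acceptance checks
# share one run, memoized for the session.
.validation_cache <- new.env(parent = emptyenv())

get_validation_study <- function() {
  if (is.null(.validation_cache$study)) {
    .validation_cache$study <- validation_study(n_reps = 50, seed = 1)
  }
  .validation_cache$study
}
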