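# Full-size synthetic cohorts (50 plants x 72 frames, no dropout) shared by
# the acceptance checks; computed once per test session, on first use.
.acceptance_cache <- new.env(parent = emptyenv())

acceptance_batch <- function(kind) {
  if (is.null(.acceptance_cache[[kind]])) {
    co <- generate_cohort(50, kind, seed = if (kind == "dicot") 101L
                          else 202L, n_frames = 72L,
                          visibility_dropout = 0)
    df <- run_batch(co$plants, build_pipeline(kind))
    .acceptance_cache[[kind]] <- list(cohort = co, table = df)
  }
  .acceptance_cache[[kind]]
}
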