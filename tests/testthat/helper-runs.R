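# The default two-class fixture pipeline run (the stated reference world) is
# used by several tests; run it once per session and reuse.
.bovw_run_cache <- new.env(parent = emptyenv())

default_pipeline_run <- function() {
  if (is.null(.bovw_run_cache$res)) {
    ds <- make_dataset(fixture_spec(seed = 11))
    .bovw_run_cache$ds <- ds
    .bovw_run_cache$res <- run_pipeline(
      ds, config = pipeline_config(embed_method = "none", seed = 11),
      verbose = FALSE
    )
  }
  list(ds = .bovw_run_cache$ds, res = .bovw_run_cache$res)
}
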