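# Fixture sets are deterministic per seed; cache them across test files.
.fx_cache <- new.env(parent = emptyenv())

shared_fixtures <- function(seed = 3L) {
  key <- as.character(seed)
  if (is.null(.fx_cache[[key]]))
    .fx_cache[[key]] <- generate_fixtures(seed = seed)
  .fx_cache[[key]]
}
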