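# The study-scale simulation grid is expensive; compute it once per test run
# and share it between the tests that need it.

.grid_cache <- new.env(parent = emptyenv())

full_grid_800 <- function() {
  if (is.null(.grid_cache$g800))
    .grid_cache$g800 <- run_grid(reps = 800, seed = 1)
  .grid_cache$g800
}
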