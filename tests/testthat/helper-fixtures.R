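## Shared fixtures: small simulated subjects built once per test run.

fixture_flows <- function(mcbf = 35, seed = 101, rel_sd = 0.12) {
  make_segment_flows(mcbf, rel_sd = rel_sd, seed = seed)
}

## memoised noiseless default subject
fixture_subject <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_subject(fixture_flows())
    cache
  }
})

## brute-force discrete-disc oracle: enumerate every pixel against the
## radius test (independent of roi_mask's construction)
brute_force_disc <- function(center, diameter_px, grid_shape) {
  hits <- NULL
  r <- diameter_px / 2
  for (i in seq_len(grid_shape[1]))
    for (j in seq_len(grid_shape[2]))
      if ((i - center[1])^2 + (j - center[2])^2 <= r^2 + 1e-9)
        hits <- rbind(hits, c(i, j))
  hits
}
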