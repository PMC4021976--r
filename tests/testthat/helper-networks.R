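# Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

brain_net <- function() {
  if (is.null(.fixtures$brain)) .fixtures$brain <- build_brain_network()
  .fixtures$brain
}

# A modest brain-network ensemble shared by observable/correlation tests.
brain_ensemble <- function() {
  if (is.null(.fixtures$ens)) {
    net <- brain_net()
    cs <- make_constraints(net, 0.15, nu_max = 1)
    .fixtures$ens <- sample_ensemble(net, cs,
                                     sampler_config(seed = 99L, K = 400L))
  }
  .fixtures$ens
}

# Fraction of feasible grid cells (from a brute-force enumeration) whose
# lattice coordinates are hit by at least one sample after snapping each
# sample's free components to the nearest grid level.
grid_coverage <- function(samples, grid) {
  free <- attr(grid, "free_cols")
  levels <- lapply(free, function(j) sort(unique(grid[, j])))
  snap_key <- function(m) {
    idx <- vapply(seq_along(free), function(q) {
      lv <- levels[[q]]
      vapply(m[, free[q]], function(v) which.min(abs(lv - v)), 0L)
    }, integer(nrow(m)))
    apply(matrix(idx, nrow(m)), 1, paste, collapse = "/")
  }
  gridk <- unique(snap_key(grid))
  sampk <- unique(snap_key(samples))
  mean(gridk %in% sampk)
}
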