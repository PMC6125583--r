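# small shared helpers

# deterministic child seed from a parent seed and a stage tag; kept in
# 32-bit integer range so set.seed() accepts it on any platform
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

# wrap an angle to [0, 2*pi)
wrap_2pi <- function(phi) phi %% (2 * pi)

# Fisher z transform with capping so r = +/-1 stays finite
fisher_z <- function(r, cap = 1 - 1e-12) atanh(pmin(pmax(r, -cap), cap))

fisher_z_inv <- function(z) tanh(z)

# select runs of one depth / direction from a list of depth_run_series
runs_at <- function(runs, depth = NULL, direction = NULL) {
  keep <- vapply(runs, function(r) {
    (is.null(depth) || abs(r$depth - depth) < 1e-9) &&
      (is.null(direction) || r$direction == direction)
  }, logical(1))
  runs[keep]
}

run_depths <- function(runs) sort(unique(vapply(runs, `[[`, numeric(1), "depth")))
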