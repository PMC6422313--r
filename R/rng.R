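# Seeded noise streams.  Every stochastic routine in the package draws from
# a stream derived deterministically from a user seed, and restores the
# caller's RNG state on exit, so simulations are reproducible and do not
# perturb the session RNG.

# Offsets keyed by controlled variable, so a uni-objective simulation and
# the matching objective inside a multi-objective simulation share the same
# noise sub-stream for that variable (makes the rho -> 1 degenerate mixture
# exactly equal to the corresponding uni-objective run).
.VAR_STREAM_OFFSET <- c(z_B = 1L, dz_B = 2L, w = 3L)

# Derive a 32-bit-safe sub-stream seed from (seed, controlled variable).
substream_seed <- function(seed, variable) {
  off <- .VAR_STREAM_OFFSET[[variable]]
  as.integer((as.double(seed) %% 1048576) * 1024 + 7L * off + 1L)
}

# Evaluate `expr` under a given seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# (N-1) x 2 matrix of standard-normal draws (columns: multiplicative nu_m,
# additive nu_a), one row per simulated transition, from the variable's
# sub-stream.
noise_stream <- function(seed, variable, n_transitions) {
  with_seed(substream_seed(seed, variable), {
    matrix(stats::rnorm(2L * n_transitions), ncol = 2L, byrow = TRUE,
           dimnames = list(NULL, c("m", "a")))
  })
}
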