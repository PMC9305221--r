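# Evaluate code under a local RNG seed, restoring the caller's RNG state.
# seed = NULL means "use the ongoing RNG stream" (no save/restore), so nested
# seeded calls compose: an outer with_seed() makes inner seed = NULL calls
# deterministic without resetting the stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = genv, inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = genv), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = genv)), add = TRUE)
  }
  set.seed(seed)
  code
}

# Derive a per-task seed from a global seed and a task counter, keeping the
# result a valid 32-bit integer. Adding a task to a batch does not perturb
# the seeds of the others.
derive_seed <- function(seed, counter) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 7919 + counter * 104729) %% 2147483647)
}
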