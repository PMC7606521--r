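# Small shared utilities.

# data.table is used via :: throughout; mark the namespace as aware so
# grouped [.data.table syntax works inside the package.
.datatable.aware <- TRUE

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
# Every stochastic operation in the package funnels through this so that
# generators and samplers are pure functions of (arguments, seed).
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Derive a child seed below 2^31 from a base seed and an index.
.child_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 1103L + as.numeric(index) * 12347L) %%
               2147483629)
}
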