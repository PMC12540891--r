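# Internal optimizer utilities.

# Run expr with a private RNG stream seeded by `seed`, restoring the caller's
# RNG state afterwards so package fits never perturb user-level randomness.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Classic rand/1/bin differential evolution on one dimension with a seeded,
# isolated RNG stream. Small populations suffice for the smooth 1-D AARD
# profiles met here; the caller polishes the incumbent deterministically.
.de_optim_1d <- function(fn, lower, upper, n_pop = 10L, n_gen = 15L,
                         seed = 1L, F = 0.8, CR = 0.9) {
  .with_seed(seed, {
    pop <- stats::runif(n_pop, lower, upper)
    val <- vapply(pop, fn, numeric(1))
    for (g in seq_len(n_gen)) {
      for (i in seq_len(n_pop)) {
        idx <- sample(setdiff(seq_len(n_pop), i), 3L)
        trial <- pop[idx[1]] + F * (pop[idx[2]] - pop[idx[3]])
        if (stats::runif(1) > CR) trial <- pop[i]
        trial <- min(max(trial, lower), upper)
        v <- fn(trial)
        if (v <= val[i]) { pop[i] <- trial; val[i] <- v }
      }
    }
    best <- which.min(val)
    list(par = pop[best], value = val[best])
  })
}
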