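# Shared fixture builders. Everything is generated in code at test time.

random_pd <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  a <- matrix(rnorm(n * n), n)
  crossprod(a) / n + diag(0.5, n)
}

random_symmetric_graph <- function(n, density = 0.5, weighted = TRUE) {
  E <- matrix(0, n, n)
  ut <- upper.tri(E)
  vals <- ifelse(runif(sum(ut)) < density,
                 if (weighted) runif(sum(ut)) else 1, 0)
  E[ut] <- vals
  E + t(E)
}

# A small, fast synthetic subject for pipeline tests: 2 runs x 300 volumes,
# 8 well-spaced events.
small_subject <- function(seed = 11, ...) {
  spec <- simulation_spec(n_runs = 2, n_events = 8, seed = seed, ...)
  simulate_cohort(list(spec))[[1]]
}
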