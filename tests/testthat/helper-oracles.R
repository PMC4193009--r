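# Independent reference implementations used as oracles. These deliberately
# use different algorithms from the package code paths they check.

# Proximal-gradient (ISTA) reference solver for the penalized Gaussian
# log-likelihood, with backtracking to stay inside the positive-definite
# cone. Slow but simple; only used for p <= 3.
ref_glasso_pg <- function(S, lambda, penalize_diagonal = TRUE,
                          max_iter = 50000, tol = 1e-10) {
  p <- nrow(S)
  Omega <- diag(1 / diag(S))
  step <- 0.1
  soft_mat <- function(m, t) {
    out <- sign(m) * pmax(abs(m) - t, 0)
    if (!penalize_diagonal) diag(out) <- diag(m)
    out
  }
  obj <- function(Om) {
    ev <- eigen(Om, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) return(Inf)
    l1 <- if (penalize_diagonal) sum(abs(Om)) else sum(abs(Om)) - sum(abs(diag(Om)))
    -sum(log(ev)) + sum(S * Om) + lambda * l1
  }
  f_old <- obj(Omega)
  for (i in seq_len(max_iter)) {
    grad <- S - solve(Omega)
    repeat {
      cand <- soft_mat(Omega - step * grad, step * lambda)
      cand <- 0.5 * (cand + t(cand))
      f_new <- obj(cand)
      if (is.finite(f_new)) break
      step <- step / 2
    }
    if (f_new > f_old - 1e-15) {
      step <- step / 2
      if (step < 1e-12) break
      next
    }
    Omega <- cand
    if (f_old - f_new < tol) { f_old <- f_new; break }
    f_old <- f_new
  }
  Omega
}

# Closed-form p = 2 graphical lasso solution with the diagonal penalized:
# W11 = s11 + lambda, W12 = sign(s12) * max(|s12| - lambda, 0).
ref_glasso_p2 <- function(S, lambda) {
  W <- S
  diag(W) <- diag(S) + lambda
  w12 <- sign(S[1, 2]) * max(abs(S[1, 2]) - lambda, 0)
  W[1, 2] <- W[2, 1] <- w12
  list(W = W, Omega = solve(W))
}

# Full-enumeration Wilcoxon signed-rank oracle via expand.grid (distinct
# code path from the package's iterative-doubling enumeration).
naive_wilcoxon <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  sums <- as.vector(signs %*% r)
  p <- 2 * min(mean(sums >= W - 1e-12), mean(sums <= W + 1e-12))
  list(statistic = W, p.value = min(1, p))
}

# Brute-force node strength: explicit double loop.
brute_strength <- function(E) {
  n <- nrow(E)
  k <- numeric(n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j) k[i] <- k[i] + E[i, j]
  k
}

# Brute-force weighted clustering coefficient: explicit triple loop over
# ordered pairs, binary degree in the denominator.
brute_clustering <- function(E) {
  n <- nrow(E)
  w <- E / max(abs(E))
  w[w < 0] <- 0
  diag(w) <- 0
  C <- numeric(n)
  for (i in seq_len(n)) {
    k <- sum(w[i, ] > 0)
    if (k < 2) next
    num <- 0
    for (j in seq_len(n)) for (h in seq_len(n)) {
      if (j == i || h == i || j == h) next
      num <- num + (w[i, j] * w[i, h] * w[j, h])^(1 / 3)
    }
    C[i] <- num / (k * (k - 1))
  }
  C
}

# Direct discrete convolution oracle for the taper: rectangle of length L
# convolved with a unit-area Gaussian sampled on +/- 4 sigma, central L
# samples, normalized.
brute_taper <- function(L, sigma) {
  K <- ceiling(4 * sigma)
  g <- exp(-((-K:K)^2) / (2 * sigma^2))
  g <- g / sum(g)
  full <- convolve(rep(1, L), rev(g), type = "open")  # length L + 2K
  w <- full[(K + 1):(K + L)]
  w / sum(w)
}
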