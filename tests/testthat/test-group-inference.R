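test_that("exact Wilcoxon matches full enumeration and its known small-sample floor", {
  # six uniformly positive differences: W+ = 21, p = 2/64
  w <- wilcoxon_signed_rank_exact(c(2, 3, 4, 5, 6, 7), rep(1, 6))
  expect_equal(w$statistic, 21)
  expect_equal(w$p.value, 0.03125)

  # swap of the two samples gives the identical two-sided p
  set.seed(2)
  x <- rnorm(8); y <- rnorm(8)
  expect_equal(wilcoxon_signed_rank_exact(x, y)$p.value,
               wilcoxon_signed_rank_exact(y, x)$p.value)

  # agreement with an independent expand.grid enumeration, ties included
  set.seed(3)
  for (n in 2:10) {
    x <- round(rnorm(n), 1); y <- round(rnorm(n), 1)
    if (all(x == y)) x[1] <- x[1] + 1
    got <- wilcoxon_signed_rank_exact(x, y)
    ref <- naive_wilcoxon(x, y)
    expect_equal(got$statistic, ref$statistic)
    expect_equal(got$p.value, ref$p.value)
  }

  expect_error(wilcoxon_signed_rank_exact(c(1, 2), c(1, 1.5)), "fewer than 2")
  expect_warning(res0 <- wilcoxon_signed_rank_exact(1:4, 1:4), "zero")
  expect_equal(res0$p.value, 1)
})

test_that("Benjamini-Hochberg control behaves like the step-up procedure", {
  f <- fdr_bh(c(0.01, 0.02, 0.5), q = 0.05)
  expect_equal(f$rejected, c(TRUE, TRUE, FALSE))
  expect_equal(fdr_bh(rep(1, 5))$rejected, rep(FALSE, 5))
  expect_true(fdr_bh(0.04, q = 0.05)$rejected)
  # BH never rejects more than the raw mask and is monotone in q
  set.seed(6)
  p <- runif(30)^2
  expect_true(all(fdr_bh(p, 0.05)$rejected <= (p <= 0.05)))
  expect_true(all(fdr_bh(p, 0.05)$rejected <= fdr_bh(p, 0.10)$rejected))
  expect_true(all(fdr_bh(p, 0.05)$rejected <= fdr_bh(p, 0.05)$rejected_q10))
  expect_error(fdr_bh(numeric(0)), "empty")
  expect_error(fdr_bh(c(0.2, 1.4)), "0, 1")
})

make_planted_nbs <- function(seed, delta = 5, noise_sd = 0.01, S = 6, N = 14) {
  set.seed(seed)
  path_edges <- cbind(1:5, 2:6)
  mats_a <- list(); mats_b <- list()
  for (s in seq_len(S)) {
    a <- matrix(rnorm(N * N, sd = noise_sd), N, N)
    a <- (a + t(a)) / 2; diag(a) <- 0
    for (k in 1:5) {
      a[path_edges[k, 1], path_edges[k, 2]] <-
        a[path_edges[k, 2], path_edges[k, 1]] <- delta + rnorm(1, sd = noise_sd)
    }
    b <- matrix(rnorm(N * N, sd = noise_sd), N, N)
    b <- (b + t(b)) / 2; diag(b) <- 0
    mats_a[[s]] <- a; mats_b[[s]] <- b
  }
  list(a = mats_a, b = mats_b)
}

test_that("NBS detects a planted component at the smallest attainable p", {
  m <- make_planted_nbs(seed = 101)
  r <- nbs_paired(m$a, m$b, n_perm = 10000)
  # the largest positive component contains the 5 planted edges
  pos <- which(r$sign > 0)
  pos <- pos[which.max(r$extents[pos])]
  comp <- r$components[[pos]]
  planted <- paste(1:5, 2:6)
  expect_true(all(planted %in% paste(comp[, 1], comp[, 2])))
  # full enumeration of 2^6 flips; only the identity and its global
  # complement keep the extent, so p sits at the two-sided floor 2/64
  expect_equal(r$n_permutations, 64L)
  expect_equal(r$p_fwe[pos], 0.03125)
  expect_true(r$significant[pos])
})

test_that("NBS p-values are invariant to a global sign flip and enumeration is deterministic", {
  m <- make_planted_nbs(seed = 202)
  r1 <- nbs_paired(m$a, m$b)
  r2 <- nbs_paired(m$b, m$a)      # all differences flipped
  expect_equal(sort(r1$p_fwe), sort(r2$p_fwe))
  expect_equal(sort(r1$extents), sort(r2$extents))
  # full enumeration ignores the seed entirely
  r3 <- nbs_paired(m$a, m$b, seed = 999)
  expect_identical(r1$p_fwe, r3$p_fwe)
  expect_identical(r1$null_max_extent, r3$null_max_extent)
})

test_that("NBS degenerate inputs behave per contract", {
  m <- make_planted_nbs(seed = 7)
  expect_message(r <- nbs_paired(m$a, m$a), "zero-variance")
  expect_length(r$extents, 0)
  expect_error(nbs_paired(m$a[1], m$a[1]), "at least 2")
})

test_that("sampled permutations include the identity so p is bounded below", {
  m <- make_planted_nbs(seed = 55, S = 16)
  r <- nbs_paired(m$a, m$b, n_perm = 200, seed = 4)
  expect_equal(r$n_permutations, 200L)
  expect_true(all(r$p_fwe >= 1 / 200))
  pos <- which(r$sign > 0)
  pos <- pos[which.max(r$extents[pos])]
  expect_true(r$significant[pos])
  # the same seed reproduces the sampled null exactly
  r2 <- nbs_paired(m$a, m$b, n_perm = 200, seed = 4)
  expect_identical(r$null_max_extent, r2$null_max_extent)
})

test_that("posterior sampling of group integration concentrates and is reproducible", {
  set.seed(17)
  n_obs <- 10000
  covs <- lapply(1:3, function(i) {
    x <- matrix(rnorm(n_obs * 4), n_obs) %*% chol(equicorrelation_matrix(4, 0.3))
    crossprod(x) / n_obs
  })
  post <- bayesian_group_integration(covs, n_obs, n_samples = 1000, seed = 9)
  expect_length(post$samples, 1000)
  plug <- mean(vapply(covs, integration, numeric(1)))
  expect_lt(abs(post$mean - plug) / plug, 0.02)
  post2 <- bayesian_group_integration(covs, n_obs, n_samples = 1000, seed = 9)
  expect_identical(post$samples, post2$samples)
  expect_error(bayesian_group_integration(covs, 5), "sample size")
})
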