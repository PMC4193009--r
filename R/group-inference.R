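#' Exact Wilcoxon signed-rank test
#'
#' Paired two-sided test by full enumeration of all `2^n` sign assignments
#' (ties receive mid-ranks), as required by the very small group sizes the
#' pipeline targets (n = 6 subjects makes asymptotic p-values invalid; the
#' minimal attainable two-sided p is then 0.03125). Zero differences are
#' dropped by the usual convention.
#'
#' @param x,y paired numeric vectors (condition a and condition b), aligned
#'   by subject.
#' @return List with `statistic` (W+, the sum of ranks of positive
#'   differences), `p.value` (two-sided, exact) and `n` (pairs used).
#' @export
wilcoxon_signed_rank_exact <- function(x, y) {
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[d != 0]
  if (length(d) == 0) {
    warning("all differences are zero; p = 1", call. = FALSE)
    return(list(statistic = 0, p.value = 1, n = 0L))
  }
  n <- length(d)
  if (n < 2) stop_woiconn("fewer than 2 nonzero differences")
  if (n > 20) stop_woiconn("exact enumeration supported for n <= 20")
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  # all subset sums of the ranks (iterative doubling)
  v <- 0
  for (ri in r) v <- c(v, v + ri)
  p <- 2 * min(mean(v >= W - 1e-12), mean(v <= W + 1e-12))
  list(statistic = W, p.value = min(1, p), n = n)
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up FDR control over one family of p-values; also reports the more
#' permissive q < 0.1 mask used for trend-level display.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return List with `adjusted` p-values, `rejected` (mask at `q`) and
#'   `rejected_q10` (mask at 0.1).
#' @export
fdr_bh <- function(p_values, q = 0.05) {
  if (!length(p_values)) stop_woiconn("empty p-value vector")
  if (any(p_values < 0 | p_values > 1)) stop_woiconn("p-values must lie in [0, 1]")
  adj <- p.adjust(p_values, method = "BH")
  list(adjusted = adj, rejected = adj <= q, rejected_q10 = adj <= 0.1)
}

# Extent (edge count) of every connected component of an undirected edge
# list; returns extents and, per edge, its component id.
component_extents <- function(edges, n_nodes) {
  if (nrow(edges) == 0)
    return(list(extents = integer(0), edge_component = integer(0)))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  if (igraph::vcount(g) < n_nodes)
    g <- igraph::add_vertices(g, n_nodes - igraph::vcount(g))
  comp <- igraph::components(g)$membership
  edge_comp <- comp[edges[, 1]]
  ext <- as.integer(table(factor(edge_comp, levels = sort(unique(edge_comp)))))
  ids <- sort(unique(edge_comp))
  list(extents = stats::setNames(ext, ids),
       edge_component = match(edge_comp, ids))
}

# t statistics for every flip pattern at once. D: S x E difference matrix,
# flips: K x S matrix of +/-1. Returns K x E matrix of t values.
flip_t_stats <- function(D, flips) {
  S <- nrow(D)
  ss <- colSums(D^2)
  m <- flips %*% D / S
  v <- sweep(-S * m^2, 2, ss, `+`) / (S - 1)
  v[v < 0] <- 0
  t_mat <- m / sqrt(v / S)
  t_mat[v == 0 & m == 0] <- 0
  t_mat
}

#' Network-based statistic for a paired two-condition design
#'
#' Per-edge paired t-tests on the within-subject condition differences are
#' thresholded at the two-sided critical value for `primary_p` (df = S - 1).
#' Connected components are formed separately among positive and negative
#' supra-threshold edges (components never mix signs) and scored by extent
#' (edge count). The permutation null flips the sign of each subject's
#' difference matrix (equivalent to permuting condition labels within
#' subject); the null statistic is the maximum component extent over both
#' signed supra-threshold graphs per flip, so one null distribution
#' simultaneously protects components of either sign and the resulting
#' p-values are exactly invariant to a global sign flip of the data. All
#' `2^S` flips are enumerated when `2^S <= n_perm` (making the result
#' deterministic); otherwise `n_perm` random flips including the identity
#' are drawn. The family-wise corrected p-value of a component is the
#' fraction of null draws whose maximum extent reaches the component's
#' extent; because the identity flip and its global complement both
#' reproduce the observed graph, the smallest attainable p under full
#' enumeration is `2/2^S` (0.03125 for S = 6, matching the floor of the
#' exact sign test at that group size).
#'
#' Edges whose differences have zero variance across subjects are excluded
#' (with a message).
#'
#' @param mats_a,mats_b per-subject symmetric matrices for the two
#'   conditions, aligned by subject.
#' @param primary_p primary edge-level threshold (default 0.05, two-sided).
#' @param n_perm permutation budget (default 10000).
#' @param alpha family-wise significance level (default 0.05).
#' @param seed RNG seed for sampled permutations.
#' @return Object of class `nbs_result`: `components` (list of edge index
#'   matrices), `extents`, `sign`, `p_fwe`, `significant`,
#'   `null_max_extent`, `n_permutations`, `threshold_t`, `excluded_edges`.
#' @export
nbs_paired <- function(mats_a, mats_b, primary_p = 0.05, n_perm = 10000,
                       alpha = 0.05, seed = 1L) {
  S <- length(mats_a)
  if (S < 2 || length(mats_b) != S)
    stop_woiconn("at least 2 subjects with aligned condition matrices required")
  N <- nrow(mats_a[[1]])
  ut <- which(upper.tri(mats_a[[1]]))
  pair_idx <- which(upper.tri(mats_a[[1]]), arr.ind = TRUE)
  D <- t(vapply(seq_len(S),
                function(s) (mats_a[[s]] - mats_b[[s]])[ut],
                numeric(length(ut))))
  sds <- apply(D, 2, sd)
  keep <- sds > 0
  n_excluded <- sum(!keep)
  if (n_excluded) message(n_excluded, " zero-variance edges excluded from NBS")
  empty <- list(components = list(), extents = integer(0),
                sign = integer(0), p_fwe = numeric(0),
                significant = logical(0), null_max_extent = integer(0),
                n_permutations = 0L,
                threshold_t = qt(1 - primary_p / 2, df = S - 1),
                excluded_edges = n_excluded, seed = seed, n_nodes = N)
  if (!any(keep)) return(structure(empty, class = "nbs_result"))
  D <- D[, keep, drop = FALSE]
  pair_idx <- pair_idx[keep, , drop = FALSE]
  t_crit <- qt(1 - primary_p / 2, df = S - 1)

  obs_t <- drop(flip_t_stats(D, matrix(1, 1, S)))
  comp_of_sign <- function(tv, sign) {
    sel <- if (sign > 0) tv > t_crit else tv < -t_crit
    component_extents(pair_idx[sel, , drop = FALSE], N)
  }
  pos <- comp_of_sign(obs_t, +1)
  neg <- comp_of_sign(obs_t, -1)

  components <- list(); extents <- integer(0); signs <- integer(0)
  gather <- function(cc, sign, sel_edges) {
    for (ci in seq_along(cc$extents)) {
      components[[length(components) + 1]] <<-
        sel_edges[cc$edge_component == ci, , drop = FALSE]
      extents <<- c(extents, cc$extents[[ci]])
      signs <<- c(signs, sign)
    }
  }
  gather(pos, +1L, pair_idx[obs_t > t_crit, , drop = FALSE])
  gather(neg, -1L, pair_idx[obs_t < -t_crit, , drop = FALSE])

  # permutation null: max component extent over both signed graphs
  if (2^S <= n_perm) {
    K <- 2^S
    flips <- as.matrix(expand.grid(rep(list(c(1, -1)), S)))
  } else {
    K <- n_perm
    flips <- with_local_seed(seed, {
      f <- matrix(sample(c(1, -1), (n_perm - 1) * S, replace = TRUE),
                  n_perm - 1, S)
      rbind(rep(1, S), f)   # identity always included
    })
  }
  t_null <- flip_t_stats(D, flips)
  max_extent_of <- function(sel) {
    ext <- component_extents(pair_idx[sel, , drop = FALSE], N)$extents
    if (length(ext)) max(ext) else 0L
  }
  null_max <- vapply(seq_len(K), function(k) {
    max(max_extent_of(t_null[k, ] > t_crit),
        max_extent_of(t_null[k, ] < -t_crit))
  }, integer(1))

  p_fwe <- vapply(extents, function(e) mean(null_max >= e), numeric(1))
  out <- empty
  out$components <- components
  out$extents <- as.integer(extents)
  out$sign <- signs
  out$p_fwe <- p_fwe
  out$significant <- p_fwe < alpha
  out$null_max_extent <- null_max
  out$n_permutations <- as.integer(K)
  structure(out, class = "nbs_result")
}

#' @export
print.nbs_result <- function(x, ...) {
  cat(sprintf("<nbs_result> %d component(s), %d permutation draws, t threshold %.3f\n",
              length(x$extents), x$n_permutations, x$threshold_t))
  if (length(x$extents))
    for (i in seq_along(x$extents))
      cat(sprintf("  component %d: %d edges (%s), p_fwe = %.4g%s\n", i,
                  x$extents[i], if (x$sign[i] > 0) "+" else "-", x$p_fwe[i],
                  if (x$significant[i]) " *" else ""))
  invisible(x)
}

#' One-sample network-based statistic
#'
#' Tests each edge of a set of subject matrices against zero by treating the
#' matrices themselves as the within-subject differences of [nbs_paired()].
#'
#' @param mats per-subject symmetric matrices.
#' @inheritParams nbs_paired
#' @return An `nbs_result`.
#' @export
nbs_one_sample <- function(mats, primary_p = 0.05, n_perm = 10000,
                           alpha = 0.05, seed = 1L) {
  zeros <- lapply(mats, function(m) matrix(0, nrow(m), ncol(m)))
  nbs_paired(mats, zeros, primary_p = primary_p, n_perm = n_perm,
             alpha = alpha, seed = seed)
}

#' Bayesian sampling of group-level integration
#'
#' For each draw, every subject's covariance is sampled from its
#' inverse-Wishart posterior under a Jeffreys prior (posterior
#' `IW(n, n * S_hat)` given `n` observations and sample covariance `S_hat`),
#' the integration of each sampled covariance is computed, and the group mean
#' over subjects is recorded. The posterior is summarized by the requested
#' number of draws (default 1000).
#'
#' @param subject_covariances list of symmetric positive-definite sample
#'   covariance matrices, one per subject.
#' @param observations_per_subject effective sample sizes (recycled);
#'   each must exceed `N + 1`.
#' @param n_samples posterior draws (default 1000).
#' @param seed RNG seed.
#' @return List with `samples` (group-level integration draws), `mean`, `sd`.
#' @export
bayesian_group_integration <- function(subject_covariances,
                                       observations_per_subject,
                                       n_samples = 1000, seed = 1L) {
  n_sub <- length(subject_covariances)
  n_obs <- rep_len(observations_per_subject, n_sub)
  N <- nrow(subject_covariances[[1]])
  if (any(n_obs <= N + 1))
    stop_woiconn("effective sample size must exceed N + 1 for a proper posterior")
  samples <- with_local_seed(seed, {
    per_subject <- vapply(seq_len(n_sub), function(j) {
      S_hat <- subject_covariances[[j]]
      scale_inv <- chol2inv(chol(n_obs[j] * S_hat))
      draws <- rWishart(n_samples, df = n_obs[j], Sigma = scale_inv)
      vapply(seq_len(n_samples), function(i) {
        Sigma <- chol2inv(chol(draws[, , i]))
        integration(Sigma)
      }, numeric(1))
    }, numeric(n_samples))
    rowMeans(per_subject)
  })
  list(samples = samples, mean = mean(samples), sd = sd(samples))
}
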