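#' Network integration
#'
#' Scalar summary of the overall statistical dependence in the network. The
#' default (`mode = "marrelec"`) is `-1/2 log det(R)` with `R` the correlation
#' normalization of the input covariance: zero for independent regions,
#' positive and growing as dependence strengthens, and invariant to
#' per-region variance rescaling. The `"literal"` mode returns
#' `+1/2 log det(M)` of the input matrix as-is.
#'
#' A Fisher-z condition matrix (zero diagonal) is converted back to a
#' correlation matrix via `tanh` with unit diagonal before the determinant is
#' taken. Near-singular inputs are repaired by flooring eigenvalues at 1e-8
#' (with a warning); an input still singular after repair is an error.
#'
#' @param M covariance/correlation matrix, or a Fisher-z matrix with zero
#'   diagonal (see `input`).
#' @param mode `"marrelec"` (default) or `"literal"`.
#' @param input `"covariance"` (default) or `"fisherz"`.
#' @return Integration in nats.
#' @export
integration <- function(M, mode = c("marrelec", "literal"),
                        input = c("covariance", "fisherz")) {
  mode <- match.arg(mode)
  input <- match.arg(input)
  if (input == "fisherz") {
    M <- tanh(M)
    diag(M) <- 1
  }
  ev <- eigen(M, symmetric = TRUE)
  if (min(ev$values) <= 1e-8) {
    warning("near-singular matrix; eigenvalues floored at 1e-8", call. = FALSE)
    vals <- pmax(ev$values, 1e-8)
    M <- ev$vectors %*% (vals * t(ev$vectors))
    M <- 0.5 * (M + t(M))
    if (min(vals) <= 0) stop_woiconn("matrix singular after repair")
  }
  if (mode == "literal")
    return(0.5 * determinant(M, logarithm = TRUE)$modulus[1])
  R <- cov2cor(M)
  -0.5 * determinant(R, logarithm = TRUE)$modulus[1]
}

#' Node strength (weighted degree)
#'
#' Row sums of the (signed) edge-weight matrix.
#'
#' @param E symmetric edge-weight matrix with zero diagonal.
#' @return Numeric vector of length N.
#' @export
node_strength <- function(E) {
  if (!is_symmetric_matrix(E, tol = 1e-8)) stop_woiconn("E must be symmetric")
  diag(E) <- 0
  rowSums(E)
}

#' Weighted clustering coefficient
#'
#' The mean triangle intensity around each node: weights are first normalized
#' to `[0, 1]` by dividing by the largest absolute weight, negative weights
#' are set to zero (with a message), and
#' `C_i = sum_{j,h} (w_ij w_ih w_jh)^{1/3} / (k_i (k_i - 1))`
#' with `k_i` the binary degree (count of nonzero links), following the Brain
#' Connectivity toolbox convention. Nodes with degree below 2 get `C_i = 0`.
#'
#' @param E symmetric edge-weight matrix with zero diagonal.
#' @return Numeric vector of per-node coefficients in `[0, 1]`.
#' @export
clustering_coefficient <- function(E) {
  if (!is_symmetric_matrix(E, tol = 1e-8)) stop_woiconn("E must be symmetric")
  diag(E) <- 0
  mx <- max(abs(E))
  if (mx == 0) return(rep(0, nrow(E)))
  w <- E / mx
  if (any(w < 0)) {
    message("negative weights set to 0 for the clustering coefficient")
    w[w < 0] <- 0
  }
  cw <- w^(1 / 3)
  num <- diag(cw %*% cw %*% cw)
  k <- rowSums(w > 0)
  C <- ifelse(k >= 2, num / (k * (k - 1)), 0)
  as.numeric(C)
}

#' Network density
#'
#' Fraction of node pairs that are significantly connected:
#' `D = |edges| / (n (n - 1) / 2)`.
#'
#' @param n_edges number of significant edges (or an edge matrix/logical
#'   adjacency whose upper triangle is counted).
#' @param n_nodes number of nodes (>= 2).
#' @return Density in `[0, 1]`.
#' @export
network_density <- function(n_edges, n_nodes) {
  if (n_nodes < 2) stop_woiconn("n_nodes must be >= 2")
  if (is.matrix(n_edges)) n_edges <- sum(n_edges[upper.tri(n_edges)] != 0)
  n_edges / (n_nodes * (n_nodes - 1) / 2)
}

#' Graph weights of a Fisher-z condition matrix
#'
#' Back-transforms a condition-mean Fisher-z matrix to the correlation scale.
#' Clustering consumes the magnitude `|tanh(z)|` (keeping coefficients in
#' `[0, 1]`); strength consumes the signed `tanh(z)`.
#'
#' @param Mz symmetric Fisher-z matrix with zero diagonal.
#' @return List with elements `signed` and `abs`.
#' @export
condition_graph <- function(Mz) {
  w <- tanh(Mz)
  diag(w) <- 0
  list(signed = w, abs = abs(w))
}

#' All graph metrics of one condition matrix
#'
#' @param Mz symmetric Fisher-z condition-mean matrix (zero diagonal).
#' @return List with `integration` (nats), `strength` (signed weighted
#'   degree), `clustering` (per-node coefficients).
#' @export
metric_set <- function(Mz) {
  g <- condition_graph(Mz)
  list(integration = integration(Mz, input = "fisherz"),
       strength = node_strength(g$signed),
       clustering = clustering_coefficient(g$abs))
}
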