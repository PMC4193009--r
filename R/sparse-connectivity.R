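#' Graphical lasso fit for one windowed covariance
#'
#' Finds the precision matrix maximizing the penalized Gaussian
#' log-likelihood `log det(Omega) - tr(S Omega) - lambda ||Omega||_1` by block
#' coordinate descent, with the l1 penalty over all entries of Omega
#' (including the diagonal) by default. Convergence is declared when the
#' duality gap falls below `tol`.
#'
#' @param S symmetric positive-semidefinite windowed covariance (a diagonal
#'   jitter of 1e-8 is added if S is singular).
#' @param lambda penalty, `>= 0`.
#' @param tol duality-gap tolerance (default 1e-5).
#' @param max_iter maximum outer sweeps (default 500); a fit that has not
#'   converged is flagged, not an error.
#' @param penalize_diagonal penalize diagonal entries too (default TRUE,
#'   matching the printed objective).
#' @return Object of class `glasso_fit`: `lambda`, `precision`, `covariance`,
#'   `objective`, `n_iterations`, `converged`.
#' @export
glasso_fit <- function(S, lambda, tol = 1e-5, max_iter = 500,
                       penalize_diagonal = TRUE) {
  if (!is_symmetric_matrix(S, tol = 1e-6)) stop_woiconn("S must be symmetric")
  if (lambda < 0) stop_woiconn("lambda must be non-negative")
  S <- 0.5 * (S + t(S))
  ev_min <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < -1e-8) stop_woiconn("S must be positive semidefinite")
  if (ev_min < 1e-10 && lambda == 0) S <- S + diag(1e-8, nrow(S))
  fit <- .glasso_cd(S, lambda, tol, as.integer(max_iter), penalize_diagonal)
  Omega <- fit$Omega
  l1 <- if (penalize_diagonal) sum(abs(Omega))
        else sum(abs(Omega)) - sum(abs(diag(Omega)))
  obj <- determinant(Omega, logarithm = TRUE)$modulus[1] -
    sum(S * Omega) - lambda * l1
  structure(
    list(lambda = lambda, precision = Omega, covariance = fit$W,
         objective = obj, n_iterations = fit$iterations,
         converged = fit$converged, dual_gap = fit$gap),
    class = "glasso_fit")
}

#' @export
print.glasso_fit <- function(x, ...) {
  nz <- sum(x$precision[upper.tri(x$precision)] != 0)
  cat(sprintf("<glasso_fit> p=%d, lambda=%.4g, %d nonzero off-diagonals, %s in %d sweeps\n",
              nrow(x$precision), x$lambda, nz,
              if (x$converged) "converged" else "NOT converged",
              x$n_iterations))
  invisible(x)
}

#' Default penalty grid for a set of windowed covariances
#'
#' 20 log-spaced values spanning `[1e-3, 1]` times the largest absolute
#' off-diagonal entry of the mean windowed covariance.
#'
#' @param windows list of windowed covariance matrices.
#' @param n_grid grid size (default 20).
#' @return Increasing numeric vector of penalties.
#' @export
lambda_grid <- function(windows, n_grid = 20) {
  S_bar <- Reduce(`+`, windows) / length(windows)
  m <- max(abs(S_bar[upper.tri(S_bar)]))
  exp(seq(log(1e-3 * m), log(m), length.out = n_grid))
}

#' Cross-validated penalty selection
#'
#' Leave-one-window-out cross-validation matched to how the penalty is later
#' used: for each penalty the graphical lasso is fitted to every window
#' individually, and each held-out window `S_ho` is scored by the mean
#' Gaussian log-likelihood `log det(Omega) - tr(S_ho Omega)` of the fits from
#' the remaining windows. The penalty maximizing the mean held-out score is
#' returned; ties go to the smaller penalty. A penalty at which any window's
#' fit fails to converge is removed from contention with a warning. Because
#' single short windows are the training data, the selected penalty reflects
#' the regularization a window of this length actually needs to generalize.
#'
#' @param windows list of at least two windowed covariance matrices (all the
#'   subject's valid windows, pooled across conditions).
#' @param grid penalty values; default [lambda_grid()].
#' @param tol,max_iter duality-gap tolerance and sweep budget for the
#'   selection fits. The defaults are looser than [glasso_fit()]'s: penalty
#'   selection only needs the argmax of a smooth score curve, and the final
#'   per-window fits at the chosen penalty are run at full precision.
#' @return The selected penalty, with the score table in attribute `cv`.
#' @export
select_lambda_cv <- function(windows, grid = NULL, tol = 1e-4,
                             max_iter = 200) {
  if (length(windows) < 2)
    stop_woiconn("cross-validation needs at least two windows")
  if (is.null(grid)) grid <- lambda_grid(windows)
  if (!length(grid)) stop_woiconn("empty penalty grid")
  grid <- sort(grid)
  n <- length(windows)
  # warm-started descending path with held-out scoring in compiled code;
  # the descent stops once the score curve has clearly passed its peak
  desc <- rev(grid)
  syms <- lapply(windows, function(S) 0.5 * (S + t(S)))
  cv <- .glasso_cv_path(syms, desc, tol, as.integer(max_iter), TRUE, 4L)
  mean_score <- rev(cv$score)            # back to ascending lambda order
  ok <- rev(cv$converged)
  seen <- rev(cv$evaluated) == 1
  mean_score[!seen | !ok] <- -Inf
  if (!any(is.finite(mean_score)))
    stop_woiconn("no penalty converged in cross-validation")
  if (any(seen & !ok))
    warning(sprintf("%d penalties removed for non-convergence",
                    sum(seen & !ok)), call. = FALSE)
  best <- which(mean_score == max(mean_score))[1]  # ties -> smaller lambda
  out <- grid[best]
  attr(out, "cv") <- data.frame(lambda = grid, score = mean_score,
                                converged = ok, evaluated = seen)
  out
}

#' Fisher transform of a regularized covariance matrix
#'
#' Normalizes the covariance to a correlation matrix, maps off-diagonal
#' entries through `atanh` (after clipping to +/- (1 - 1e-7)), and sets the
#' diagonal to zero by convention.
#'
#' @param W symmetric positive-definite covariance matrix.
#' @return Symmetric matrix of Fisher-z values with zero diagonal.
#' @export
fisher_transform_matrix <- function(W) {
  if (!is_symmetric_matrix(W, tol = 1e-6)) stop_woiconn("W must be symmetric")
  if (min(eigen(W, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop_woiconn("W must be positive definite")
  R <- cov2cor(W)
  R <- pmin(pmax(R, -(1 - 1e-7)), 1 - 1e-7)
  Z <- atanh(R)
  diag(Z) <- 0
  0.5 * (Z + t(Z))
}

#' Condition-mean connectivity matrices via a general linear model
#'
#' Vectorizes the upper triangle of every window's Fisher-z matrix, fits an
#' ordinary least-squares GLM with one indicator column per condition, and
#' reshapes each condition's coefficient vector back into a symmetric matrix.
#' With an indicator design the coefficients equal the per-condition
#' arithmetic means, which is asserted as a cross-check.
#'
#' @param z_matrices list of symmetric matrices (one per window).
#' @param conditions character vector of condition labels, one per window.
#' @param required condition labels that must all be present (default: the
#'   four windows-of-interest conditions); a missing one is an error naming
#'   it.
#' @return Named list of symmetric condition-mean matrices, one per required
#'   condition.
#' @export
condition_mean_glm <- function(z_matrices, conditions,
                               required = woi_conditions()) {
  stopifnot(length(z_matrices) == length(conditions))
  missing_cond <- setdiff(required, unique(conditions))
  if (length(missing_cond))
    stop_woiconn("no windows for condition: ",
                 paste(missing_cond, collapse = ", "))
  N <- nrow(z_matrices[[1]])
  ut <- upper.tri(z_matrices[[1]], diag = TRUE)
  Y <- t(vapply(z_matrices, function(m) m[ut], numeric(sum(ut))))
  X <- sapply(required, function(cond) as.numeric(conditions == cond))
  beta <- lm.fit(X, Y)$coefficients
  out <- list()
  for (cond in required) {
    m <- matrix(0, N, N)
    m[ut] <- beta[cond, ]
    m <- m + t(m) - diag(diag(m))
    # indicator-design OLS must equal the per-condition mean
    ref <- Reduce(`+`, z_matrices[conditions == cond]) /
      sum(conditions == cond)
    stopifnot(max(abs(m - ref)) < 1e-8)
    out[[cond]] <- m
  }
  out
}

#' Write a square matrix as TSV with a JSON sidecar
#'
#' @param m matrix to write.
#' @param path TSV path; the sidecar replaces the extension with `.json`.
#' @param meta named list of metadata (penalty, condition, subject, ...).
#' @return The TSV path, invisibly.
#' @export
write_matrix_tsv <- function(m, path, meta = list()) {
  write.table(format(as.data.frame(m), digits = 10, trim = TRUE), path,
              sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  if (length(meta)) {
    side <- sub("\\.[^.]*$", ".json", path)
    jsonlite::write_json(meta, side, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
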