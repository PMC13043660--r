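#' Drop individuals with mostly-missing cytokine panels
#'
#' Individuals with strictly more than \code{max_missing_fraction} of their
#' cytokine entries missing are removed before imputation.
#'
#' @param panel numeric matrix, individuals x cytokines.
#' @param max_missing_fraction threshold (default 0.8).
#' @return the filtered panel.
#' @export
filter_missing_individuals <- function(panel, max_missing_fraction = 0.8) {
  frac <- rowMeans(is.na(panel))
  keep <- frac <= max_missing_fraction
  if (!any(keep)) stop("every individual exceeds the missingness threshold",
                       call. = FALSE)
  panel[keep, , drop = FALSE]
}

#' SoftImpute matrix completion
#'
#' Nuclear-norm-regularized matrix completion by iterative soft-thresholded
#' SVD: missing cells are initialized at zero; each iteration takes the
#' full SVD of the current completion, shrinks every singular value by
#' lambda (floored at zero), rebuilds the matrix, and restores the observed
#' cells. Iterations stop when the relative Frobenius change of the
#' missing-cell block drops below \code{tol} or at \code{max_iter}
#' (flagged, not fatal). Inputs are expected standardized; observed cells
#' are never modified.
#'
#' @param X numeric matrix with NA for missing cells.
#' @param lambda non-negative shrinkage applied to the singular values.
#' @param max_iter iteration cap (default 500).
#' @param tol relative Frobenius tolerance on the missing block (1e-5).
#' @return list of class \code{softimpute_result}: \code{completed},
#'   \code{iterations}, \code{converged}, \code{objective} (per-iteration
#'   value of the penalized objective 0.5*||P_obs(X - Z)||_F^2 +
#'   lambda*||Z||_*).
#' @export
soft_impute <- function(X, lambda, max_iter = 500L, tol = 1e-5) {
  if (lambda < 0) stop("lambda must be >= 0", call. = FALSE)
  miss <- is.na(X)
  if (!any(miss)) {
    if (lambda == 0)
      return(structure(list(completed = X, iterations = 0L, converged = TRUE,
                            objective = numeric(0)),
                       class = "softimpute_result"))
  }
  Z <- X
  Z[miss] <- 0
  objective <- numeric(0)
  converged <- FALSE
  iterations <- 0L
  prev_miss <- Z[miss]
  for (it in seq_len(max_iter)) {
    iterations <- it
    sv <- svd(Z)
    d <- pmax(sv$d - lambda, 0)
    Zn <- sv$u %*% (d * t(sv$v))
    objective <- c(objective,
                   0.5 * sum((X[!miss] - Zn[!miss])^2) + lambda * sum(d))
    Zn[!miss] <- X[!miss]
    if (any(miss)) {
      new_miss <- Zn[miss]
      denom <- sqrt(sum(prev_miss^2))
      delta <- sqrt(sum((new_miss - prev_miss)^2))
      Z <- Zn
      if (denom == 0 && delta == 0 || (denom > 0 && delta / denom < tol)) {
        converged <- TRUE
        break
      }
      prev_miss <- new_miss
    } else {
      conv <- sqrt(sum((Zn - Z)^2)) / max(sqrt(sum(Z^2)), .Machine$double.eps)
      Z <- Zn
      if (conv < tol) { converged <- TRUE; break }
    }
  }
  if (!converged) warning("soft_impute did not converge in ", max_iter,
                          " iterations")
  structure(list(completed = Z, iterations = iterations,
                 converged = converged, objective = objective),
            class = "softimpute_result")
}

#' Tune the SoftImpute regularization parameter
#'
#' Candidate values are lambda = sigma_1 / K for K in \code{k_grid}, with
#' sigma_1 the largest singular value of the zero-filled input. Per repeat,
#' one observed value per column is masked uniformly at random, the matrix
#' is imputed at each candidate lambda, and the mean squared error on the
#' masked cells is recorded; the lambda minimizing the mean MSE wins.
#'
#' @param X standardized matrix with NA for missing cells; every column
#'   needs at least 2 observed values.
#' @param k_grid divisors of sigma_1 (default \{1.5, 2, 4, 10, 50, 100\}).
#' @param n_repeats masking repeats per lambda (default 100; the reference
#'   protocol uses 1000).
#' @param seed integer seed.
#' @param max_iter,tol passed to \code{\link{soft_impute}}.
#' @return list: \code{best_lambda}, \code{mse_table} (data.frame K,
#'   lambda, mean_mse), \code{sigma1}.
#' @export
tune_lambda <- function(X, k_grid = c(1.5, 2, 4, 10, 50, 100),
                        n_repeats = 100L, seed = 1L,
                        max_iter = 500L, tol = 1e-5) {
  if (any(k_grid <= 1)) stop("k_grid values must exceed 1", call. = FALSE)
  obs_per_col <- colSums(!is.na(X))
  if (any(obs_per_col < 2)) stop("every column needs >= 2 observed values",
                                 call. = FALSE)
  Z0 <- X; Z0[is.na(Z0)] <- 0
  sigma1 <- svd(Z0, nu = 0, nv = 0)$d[1]
  lambdas <- sigma1 / k_grid
  mse <- matrix(NA_real_, nrow = n_repeats, ncol = length(lambdas))
  withr::with_seed(seed, {
    for (r in seq_len(n_repeats)) {
      Xm <- X
      masked_idx <- vapply(seq_len(ncol(X)), function(j) {
        obs <- which(!is.na(X[, j]))
        obs[sample.int(length(obs), 1L)]
      }, integer(1))
      truth <- X[cbind(masked_idx, seq_len(ncol(X)))]
      Xm[cbind(masked_idx, seq_len(ncol(X)))] <- NA
      for (li in seq_along(lambdas)) {
        comp <- suppressWarnings(
          soft_impute(Xm, lambdas[li], max_iter = max_iter, tol = tol))$completed
        imput <- comp[cbind(masked_idx, seq_len(ncol(X)))]
        mse[r, li] <- mean((imput - truth)^2)
      }
    }
  })
  mean_mse <- colMeans(mse)
  best <- which.min(mean_mse)
  list(best_lambda = lambdas[best],
       mse_table = data.frame(K = k_grid, lambda = lambdas,
                              mean_mse = mean_mse),
       sigma1 = sigma1)
}

#' RMSE skill score relative to mean imputation
#'
#' skill = 1 - RMSE_model / RMSE_mean per column, evaluated on cells whose
#' ground truth is known (simulation setting). Columns with RMSE_mean = 0
#' are reported missing.
#'
#' @param completed model-completed matrix.
#' @param truth ground-truth matrix.
#' @param mask logical matrix marking the cells that were imputed.
#' @return named numeric vector of per-column skill scores.
#' @export
rmse_skill <- function(completed, truth, mask) {
  stopifnot(all(dim(completed) == dim(truth)), all(dim(mask) == dim(truth)))
  col_means <- colMeans(ifelse(mask, NA, truth), na.rm = TRUE)
  vapply(seq_len(ncol(truth)), function(j) {
    cells <- which(mask[, j])
    if (!length(cells)) return(NA_real_)
    rmse_model <- sqrt(mean((completed[cells, j] - truth[cells, j])^2))
    rmse_mean <- sqrt(mean((col_means[j] - truth[cells, j])^2))
    if (rmse_mean == 0) return(NA_real_)
    1 - rmse_model / rmse_mean
  }, numeric(1), USE.NAMES = FALSE) |>
    stats::setNames(colnames(truth))
}
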