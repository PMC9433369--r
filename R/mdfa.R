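# Matrix-decomposition factor analysis: X = F Lambda' + S Theta + E minimized
# in least squares over scores and parameters jointly, with [F, S] constrained
# to be columnwise orthonormal (times sqrt(n)). The solution depends on the
# data only through the covariance matrix, so fitting works from a surrogate
# root X* with X*'X* = n C.

# Surrogate root with r >= m + p rows: sqrt(n) * [C^{1/2}; 0].
surrogate_root <- function(C, n, m, rows = NULL) {
  p <- ncol(C)
  r <- if (is.null(rows)) m + p else rows
  if (r < m + p) stop("surrogate root needs at least m + p rows", call. = FALSE)
  Xs <- matrix(0, r, p)
  Xs[seq_len(p), ] <- sqrt(n) * compfa_sqrtm(C)
  Xs
}

mdfa_loss <- function(n, Xs, Z, A) sum((Xs - tcrossprod(Z, A))^2) / n

#' Matrix-decomposition factor analysis
#'
#' Fits the comprehensive factor model `X = F Lambda' + S Theta + E` by
#' alternating least squares over the joint score matrix `Z = [F, S]`
#' (constrained to `Z'Z = n I`) and the parameter block `A = [Lambda, Theta]`.
#' The score update is the orthogonal-Procrustes solution from the thin SVD of
#' `X* A`, and the parameter update is the exact conditional minimizer
#' `Lambda = X*'F / n`, `Theta = diag(S'X*) / n`. The error covariance is
#' recovered as `E'E / n` with `E = X* - F Lambda' - S Theta`; its diagonal is
#' absorbed into the specific-variance estimate at the optimum, which is why
#' this estimator's `diag_var` tracks the sum of the generating specific and
#' error variances rather than the specific variances alone.
#'
#' @inheritParams fit_lvfa_ls
#' @param root optional user-supplied surrogate root, an r x p matrix with
#'   `crossprod(root) = n * C` and `r >= m + p`; by default the zero-padded
#'   symmetric square root is used. The fitted loss and parameters do not
#'   depend on which root is chosen.
#' @return A `compfa_fit` with `method = "MDFA"`, including `error_cov`,
#'   `scores` (`Z`), and the surrogate root used.
#' @export
fit_mdfa <- function(cov, m, opts = compfa_options(), n = NULL, root = NULL) {
  cov <- if (inherits(cov, "compfa_cov")) cov else compfa_cov(cov, n)
  C <- cov$C
  p <- cov$p
  nn <- cov$n
  if (m < 1 || m >= p) stop("`m` must satisfy 1 <= m < p", call. = FALSE)
  if (is.null(root)) {
    Xs <- surrogate_root(C, nn, m)
  } else {
    Xs <- as.matrix(root)
    if (ncol(Xs) != p || nrow(Xs) < m + p) {
      stop("`root` must be r x p with r >= m + p", call. = FALSE)
    }
    if (max(abs(crossprod(Xs) / nn - C)) > 1e-8 * max(1, max(abs(C)))) {
      stop("`root` is not a root of n * C", call. = FALSE)
    }
  }

  best <- NULL
  for (start in seq_len(opts$n_starts)) {
    # init: leading eigenpairs for Lambda, residual diagonal for Theta
    e <- compfa_eigen(C)
    L <- e$vectors[, seq_len(m), drop = FALSE] %*%
      diag(sqrt(pmax(e$values[seq_len(m)], 0)), m)
    if (start > 1L) {
      L <- L * matrix(runif_local(p * m, 0.7, 1.3, seed = opts$seed + start),
                      p, m)
    }
    th <- sqrt(pmax(diag(C - tcrossprod(L)), 0.01))
    A <- cbind(L, diag(th, p))
    # first score step to make (Z, A) consistent
    sv <- svd(Xs %*% A, nu = m + p, nv = m + p)
    Z <- sqrt(nn) * sv$u %*% t(sv$v)
    loss <- mdfa_loss(nn, Xs, Z, A)
    trace <- loss
    converged <- FALSE
    iters <- 0L
    for (it in seq_len(opts$max_iter)) {
      # parameter step: exact conditional minimizers under Z'Z = n I
      Fm <- Z[, seq_len(m), drop = FALSE]
      S <- Z[, m + seq_len(p), drop = FALSE]
      L <- crossprod(Xs, Fm) / nn
      th <- colSums(S * Xs) / nn           # diag(S'X*)/n, sign-unconstrained
      A <- cbind(L, diag(th, p))
      # score step: orthogonal Procrustes on X* A
      sv <- svd(Xs %*% A, nu = m + p, nv = m + p)
      Z <- sqrt(nn) * sv$u %*% t(sv$v)
      new_loss <- mdfa_loss(nn, Xs, Z, A)
      trace <- c(trace, new_loss)
      iters <- it
      if (abs(loss - new_loss) <= opts$tol * max(loss, .Machine$double.eps)) {
        loss <- new_loss
        converged <- TRUE
        break
      }
      loss <- new_loss
    }
    if (is.null(best) || loss < best$loss) {
      best <- list(L = L, th = th, Z = Z, loss = loss, iters = iters,
                   converged = converged, trace = trace)
    }
  }

  # close with a parameter step so the stationarity identities
  # F'E = O and diag(S'E) = 0 hold exactly at the returned solution
  Fm <- best$Z[, seq_len(m), drop = FALSE]
  S <- best$Z[, m + seq_len(p), drop = FALSE]
  L <- crossprod(Xs, Fm) / nn
  th <- colSums(S * Xs) / nn
  E <- Xs - tcrossprod(Fm, L) - S %*% diag(th, p)
  loss <- sum(E^2) / nn
  error_cov <- crossprod(E) / nn
  new_compfa_fit(
    "MDFA", L, th^2, (error_cov + t(error_cov)) / 2, loss,
    best$iters, best$converged, c(best$trace, loss),
    extra = list(theta = th, scores = best$Z, surrogate_root = Xs, E = E)
  )
}

#' Orthogonality diagnostics for a fitted MDFA model
#'
#' Reports how far the fitted score system is from the comprehensive-model
#' orthogonality assumptions: `max |F'E|` and `max |diag(S'E)|` are zero at any
#' converged solution, while the off-diagonal part of `S'E` is generally
#' nonzero - the structural gap that the completely decomposed estimator
#' closes.
#'
#' @param fit a `compfa_fit` from [fit_mdfa()].
#' @return A tibble with columns `max_FtE`, `max_diag_StE`,
#'   `max_offdiag_StE`.
#' @export
mdfa_diagnostics <- function(fit) {
  stopifnot(inherits(fit, "compfa_fit"), fit$method == "MDFA")
  m <- ncol(fit$loadings)
  p <- nrow(fit$loadings)
  Fm <- fit$scores[, seq_len(m), drop = FALSE]
  S <- fit$scores[, m + seq_len(p), drop = FALSE]
  FtE <- crossprod(Fm, fit$E)
  StE <- crossprod(S, fit$E)
  tibble::tibble(
    max_FtE = max(abs(FtE)),
    max_diag_StE = max(abs(diag(StE))),
    max_offdiag_StE = max(abs(StE - diag(diag(StE), p)))
  )
}
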