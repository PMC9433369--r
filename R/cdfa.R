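# Completely decomposed factor analysis. The specific variances come from
# minimum-rank factor analysis (MRFA): choose theta2 >= 0 with C - diag(theta2)
# positive semidefinite so that the sum of the p - m smallest eigenvalues of
# the reduced matrix is minimal. The loadings then follow from the m leading
# eigenpairs of C - diag(theta2), and the residual C - LL' - diag(theta2) is
# the estimated error covariance. At this solution common factors, specific
# factors, and errors are mutually orthogonal score systems.

reduced_eigs <- function(C, theta2) {
  compfa_eigen(C - diag(theta2, length(theta2)))
}

mrfa_objective <- function(C, theta2, m) {
  d <- reduced_eigs(C, theta2)$values
  sum(d[(m + 1):length(d)])
}

# Barrier-augmented objective and gradient for the minimum-rank program.
# Returns Inf outside the strictly feasible region.
mrfa_barrier_fn <- function(C, theta2, m, mu) {
  p <- length(theta2)
  if (any(theta2 <= 0)) return(list(value = Inf))
  e <- reduced_eigs(C, theta2)
  d <- e$values
  if (d[p] <= 0) return(list(value = Inf))
  value <- sum(d[(m + 1):p]) - mu * sum(log(d)) - mu * sum(log(theta2))
  W <- e$vectors
  u <- rowSums(W[, (m + 1):p, drop = FALSE]^2)
  Minv_diag <- rowSums(sweep(W, 2, d, `/`) * W)
  grad <- -u + mu * Minv_diag - mu / theta2
  list(value = value, grad = grad, obj = sum(d[(m + 1):p]))
}

#' Minimum-rank factor analysis
#'
#' Estimates nonnegative specific variances `theta2` such that the reduced
#' matrix `C - diag(theta2)` remains positive semidefinite while the sum of
#' its `p - m` smallest eigenvalues - the common variance left unexplained by
#' `m` factors - is minimized. The program is solved by an interior-point
#' scheme: a log-determinant barrier on the reduced matrix plus a log barrier
#' on `theta2`, driven to zero over a geometric schedule, with
#' Barzilai-Borwein gradient steps and backtracking inside each stage. The
#' minimizer lies on the positive-semidefinite boundary (the reduced matrix
#' loses rank there), which the vanishing barrier approaches from inside.
#'
#' @inheritParams fit_lvfa_ls
#' @return A list of class `mrfa_fit`: `theta2`, `reduced_eigs` (decreasing
#'   eigenvalues of the reduced matrix), `objective` (sum of the `p - m`
#'   smallest), `iters`, `converged`.
#' @export
fit_mrfa <- function(cov, m, opts = compfa_options(), n = NULL) {
  cov <- if (inherits(cov, "compfa_cov")) cov else compfa_cov(cov, n)
  C <- cov$C
  p <- cov$p
  if (m < 1 || m >= p) stop("`m` must satisfy 1 <= m < p", call. = FALSE)

  scale_c <- mean(diag(C))
  ev_min <- min(eigen(C, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min <= 0) {
    # start strictly inside by shrinking toward zero specific variance
    theta2 <- rep(1e-8 * scale_c, p)
  } else {
    theta2 <- rep(min(0.4 * ev_min, 0.1 * scale_c), p)
  }

  total_iters <- 0L
  converged <- TRUE
  mus <- scale_c * 10^seq(-1, -10, by = -1)
  for (mu in mus) {
    fb <- mrfa_barrier_fn(C, theta2, m, mu)
    if (!is.finite(fb$value)) {
      theta2 <- pmax(theta2 * 0.5, 1e-12)
      fb <- mrfa_barrier_fn(C, theta2, m, mu)
    }
    g_old <- NULL
    t_bb <- 0.1 * scale_c / max(abs(fb$grad), 1)
    for (it in 1:200) {
      g <- fb$grad
      if (!is.null(g_old)) {
        dth <- theta2 - th_old
        dg <- g - g_old
        denom <- sum(dg * dg)
        t_bb <- if (denom > 0) abs(sum(dth * dg)) / denom else t_bb
        t_bb <- min(max(t_bb, 1e-12), 1e3)
      }
      th_old <- theta2
      g_old <- g
      step <- t_bb
      accepted <- FALSE
      for (bt in 1:60) {
        cand <- theta2 - step * g
        fc <- mrfa_barrier_fn(C, cand, m, mu)
        if (is.finite(fc$value) && fc$value < fb$value) {
          theta2 <- cand
          fprev <- fb$value
          fb <- fc
          accepted <- TRUE
          break
        }
        step <- step / 2
      }
      total_iters <- total_iters + 1L
      if (!accepted) break
      if (abs(fprev - fb$value) < 1e-12 * max(1, abs(fb$value))) break
    }
  }

  # land exactly on the feasible set
  theta2 <- pmax(theta2, 0)
  d <- reduced_eigs(C, theta2)$values
  if (d[p] < 0) theta2 <- theta2 + d[p]  # uniform shrink restores PSD
  theta2 <- pmax(theta2, 0)
  d <- reduced_eigs(C, theta2)$values
  structure(
    list(theta2 = theta2, reduced_eigs = d,
         objective = sum(d[(m + 1):p]), m = m, iters = total_iters,
         converged = converged),
    class = "mrfa_fit"
  )
}

#' @export
print.mrfa_fit <- function(x, ...) {
  cat(sprintf("<mrfa_fit> m = %d, objective = %.6g, converged = %s\n",
              x$m, x$objective, x$converged))
  invisible(x)
}

#' Completely decomposed factor analysis
#'
#' Two-stage estimator for the comprehensive factor model in which common
#' factors, specific factors, and errors come out mutually orthogonal: the
#' specific variances are the minimum-rank solution from [fit_mrfa()], and
#' the loadings are the `m` leading eigenvectors of `C - diag(theta2)` scaled
#' by the square roots of their eigenvalues. The error covariance is the
#' residual `C - Lambda Lambda' - diag(theta2)` and the loss is its trace,
#' which equals the minimum-rank objective.
#'
#' @inheritParams fit_lvfa_ls
#' @return A `compfa_fit` with `method = "CDFA"`, carrying the `mrfa_fit` as
#'   `$mrfa`.
#' @export
fit_cdfa <- function(cov, m, opts = compfa_options(), n = NULL) {
  cov <- if (inherits(cov, "compfa_cov")) cov else compfa_cov(cov, n)
  C <- cov$C
  p <- cov$p
  mr <- fit_mrfa(cov, m, opts)
  e <- reduced_eigs(C, mr$theta2)
  d <- e$values[seq_len(m)]
  if (any(d <= 0)) {
    stop("fewer than m positive eigenvalues in the reduced matrix",
         call. = FALSE)
  }
  L <- e$vectors[, seq_len(m), drop = FALSE] %*% diag(sqrt(d), m)
  error_cov <- C - tcrossprod(L) - diag(mr$theta2, p)
  error_cov <- (error_cov + t(error_cov)) / 2
  new_compfa_fit(
    "CDFA", L, mr$theta2, error_cov, sum(diag(error_cov)), mr$iters,
    mr$converged, NULL, extra = list(mrfa = mr)
  )
}

#' Reconstruct explicit score matrices for a CDFA solution
#'
#' Builds common-factor, specific-factor, and error score matrices `F`, `S`,
#' `E` realizing a fitted CDFA solution in an `rows`-dimensional observation
#' space, such that all model orthogonality constraints hold: `F'F = n I`,
#' `S'S = n I`, `F'S = O`, `F'E = O`, and - the completely-decomposed
#' property - the full matrix `S'E = O`. The construction factorizes the
#' joint Gram matrix of `[X, S]`, which is positive semidefinite exactly
#' because the minimum-rank step keeps `C - diag(theta2)` positive
#' semidefinite; its rank can reach `p + rank(C - diag(theta2))`, so the
#' default `rows` is `max(m + p, 2p)` rather than the minimal `m + p`.
#'
#' @param cov the `compfa_cov` the solution was fitted to.
#' @param fit a `compfa_fit` with `method = "CDFA"`.
#' @param rows number of score rows, at least `m + p`.
#' @return A list with matrices `X` (a root of `n C` compatible with the
#'   scores), `F`, `S`, `E`.
#' @export
reconstruct_scores <- function(cov, fit, rows = NULL) {
  stopifnot(inherits(fit, "compfa_fit"))
  if (fit$method != "CDFA") {
    stop("score reconstruction with full orthogonality is defined for CDFA ",
         "solutions", call. = FALSE)
  }
  cov <- if (inherits(cov, "compfa_cov")) cov else
    compfa_cov(cov, nrow(cov) + 1L)
  C <- cov$C
  nn <- cov$n
  p <- cov$p
  m <- ncol(fit$loadings)
  if (is.null(rows)) rows <- max(m + p, 2L * p)
  if (rows < m + p) stop("`rows` must be at least m + p", call. = FALSE)
  th <- sqrt(pmax(fit$diag_var, 0))
  # joint Gram of [X, S] under S'S = n I and S'X = n Theta
  G <- rbind(cbind(C, diag(th, p)), cbind(diag(th, p), diag(p)))
  eg <- compfa_eigen(G)
  keep <- which(eg$values > 1e-12 * max(eg$values))
  if (rows < length(keep)) {
    stop("`rows` too small to host the joint score system (needs ",
         length(keep), ")", call. = FALSE)
  }
  Root <- eg$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(eg$values[keep]), length(keep))
  M <- matrix(0, rows, 2L * p)
  M[seq_along(keep), ] <- sqrt(nn) * t(Root)
  X <- M[, seq_len(p), drop = FALSE]
  S <- M[, p + seq_len(p), drop = FALSE]
  sv <- svd(X - S %*% diag(th, p), nu = m, nv = m)
  Fm <- sqrt(nn) * sv$u
  # align F's sign convention with the fitted loadings via X'F/n = Lambda
  Lhat <- crossprod(X, Fm) / nn
  sgn <- sign(colSums(Lhat * fit$loadings))
  sgn[sgn == 0] <- 1
  Fm <- Fm %*% diag(sgn, m)
  E <- X - tcrossprod(Fm, fit$loadings) - S %*% diag(th, p)
  list(X = X, F = Fm, S = S, E = E)
}
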