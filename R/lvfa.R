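# Latent-variable factor analysis: the classical model C = Lambda Lambda' +
# Psi^2 with a diagonal unique-variance matrix, fitted either by least squares
# on the covariance discrepancy or by maximum likelihood (EM).

lvfa_start_psi2 <- function(dC, opts, start) {
  if (start == 1L) return(0.5 * dC)
  # further starts perturb uniformly in [0.2, 0.8] * diag(C), seeded
  runif_local(length(dC), 0.2, 0.8, seed = opts$seed + start) * dC
}

# Draw uniforms under a local, restored RNG state.
runif_local <- function(n, min, max, seed) {
  had <- exists(".Random.seed", envir = globalenv())
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else rm(list = ".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  stats::runif(n, min, max)
}

# Leading-m factor step: eigendecompose C - diag(psi2), keep the m leading
# eigenpairs, truncate negative retained eigenvalues to zero.
principal_factor_step <- function(C, psi2, m) {
  e <- compfa_eigen(C - diag(psi2, length(psi2)))
  d <- pmax(e$values[seq_len(m)], 0)
  e$vectors[, seq_len(m), drop = FALSE] %*% diag(sqrt(d), m)
}

ls_loss <- function(C, L, psi2) {
  R <- C - tcrossprod(L) - diag(psi2, length(psi2))
  sum(R^2)
}

#' Least-squares latent-variable factor analysis
#'
#' Minimizes the squared Frobenius discrepancy between the sample covariance
#' and the model structure `Lambda Lambda' + diag(psi2)` by principal-factor
#' iteration: the loadings are updated from the m leading eigenpairs of
#' `C - diag(psi2)` (negative retained eigenvalues truncated to zero) and the
#' unique variances from the stationarity condition
#' `psi2 = diag(C - Lambda Lambda')`. The unique variances are deliberately
#' unconstrained in sign, so Heywood-type improper solutions are detectable
#' through `proper = FALSE` rather than masked.
#'
#' @param cov a `compfa_cov` object (or a matrix, validated with `n`).
#' @param m number of common factors, `1 <= m < p`.
#' @param opts a [compfa_options()] list.
#' @param n sample size, only used when `cov` is a raw matrix.
#' @return A `compfa_fit` with `method = "LVFA-LS"`; `error_cov` is `NULL`
#'   because the unique part absorbs specific and error variance jointly.
#' @export
fit_lvfa_ls <- function(cov, m, opts = compfa_options(), n = NULL) {
  cov <- if (inherits(cov, "compfa_cov")) cov else compfa_cov(cov, n)
  C <- cov$C
  p <- cov$p
  if (m < 1 || m >= p) stop("`m` must satisfy 1 <= m < p", call. = FALSE)

  best <- NULL
  dC <- diag(C)
  for (start in seq_len(opts$n_starts)) {
    psi2 <- lvfa_start_psi2(dC, opts, start)
    L <- principal_factor_step(C, psi2, m)
    loss <- ls_loss(C, L, psi2)
    trace <- loss
    converged <- FALSE
    iters <- 0L
    for (it in seq_len(opts$max_iter)) {
      L <- principal_factor_step(C, psi2, m)
      psi2 <- diag(C - tcrossprod(L))
      new_loss <- ls_loss(C, L, psi2)
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
      best <- list(L = L, psi2 = psi2, loss = loss, iters = iters,
                   converged = converged, trace = trace)
    }
  }
  new_compfa_fit("LVFA-LS", best$L, best$psi2, NULL, best$loss, best$iters,
                 best$converged, best$trace)
}

ml_loss <- function(C, L, psi2) {
  S <- tcrossprod(L) + diag(psi2, length(psi2))
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(ch)) return(Inf)
  Sinv <- chol2inv(ch)
  M <- C %*% Sinv
  d <- determinant(M, logarithm = TRUE)
  sum(diag(M)) - as.numeric(d$modulus) - nrow(C)
}

#' Maximum-likelihood latent-variable factor analysis
#'
#' Minimizes the normal-theory discrepancy
#' `tr(C Sigma^-1) - log|C Sigma^-1| - p` with `Sigma = Lambda Lambda' +
#' diag(psi2)` by an EM iteration on the covariance matrix. The unique
#' variances are floored at `opts$variance_floor`, which keeps `Sigma`
#' invertible; the loss is zero exactly when the model reproduces `C`.
#'
#' @inheritParams fit_lvfa_ls
#' @return A `compfa_fit` with `method = "LVFA-ML"`.
#' @export
fit_lvfa_ml <- function(cov, m, opts = compfa_options(), n = NULL) {
  cov <- if (inherits(cov, "compfa_cov")) cov else compfa_cov(cov, n)
  C <- cov$C
  p <- cov$p
  if (m < 1 || m >= p) stop("`m` must satisfy 1 <= m < p", call. = FALSE)
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12 * max(ev)) {
    stop("maximum-likelihood fitting requires a strictly positive definite ",
         "covariance matrix", call. = FALSE)
  }

  best <- NULL
  dC <- diag(C)
  floorv <- opts$variance_floor
  for (start in seq_len(opts$n_starts)) {
    psi2 <- pmax(lvfa_start_psi2(dC, opts, start), floorv)
    L <- principal_factor_step(C, psi2, m)
    loss <- ml_loss(C, L, psi2)
    trace <- loss
    converged <- FALSE
    iters <- 0L
    for (it in seq_len(opts$max_iter)) {
      # EM update for the normal factor model, covariance-only form
      Sigma <- tcrossprod(L) + diag(psi2, p)
      Sinv <- chol2inv(chol(Sigma))
      B <- t(L) %*% Sinv                    # m x p regression of f on x
      CB <- C %*% t(B)                      # p x m, E[x f']
      M <- diag(m) - B %*% L + B %*% CB     # E[f f'] given the data
      Lnew <- CB %*% solve((M + t(M)) / 2)
      psi2 <- pmax(diag(C) - rowSums(Lnew * CB), floorv)
      L <- Lnew
      new_loss <- ml_loss(C, L, psi2)
      trace <- c(trace, new_loss)
      iters <- it
      if (is.finite(new_loss) &&
          abs(loss - new_loss) <= opts$tol * max(abs(loss), .Machine$double.eps)) {
        loss <- new_loss
        converged <- TRUE
        break
      }
      loss <- new_loss
    }
    # quasi-Newton polish: EM's linear tail can leave the last digits of the
    # optimum unresolved; a short BFGS run from the EM point squeezes them
    par0 <- c(as.vector(L), log(pmax(psi2, floorv)))
    fn <- function(par) {
      Lp <- matrix(par[seq_len(p * m)], p, m)
      pp <- exp(par[p * m + seq_len(p)])
      v <- ml_loss(C, Lp, pp)
      if (is.finite(v)) v else 1e10
    }
    gr <- function(par) {
      Lp <- matrix(par[seq_len(p * m)], p, m)
      pp <- exp(par[p * m + seq_len(p)])
      Sigma <- tcrossprod(Lp) + diag(pp, p)
      ch <- tryCatch(chol(Sigma), error = function(e) NULL)
      if (is.null(ch)) return(rep(0, length(par)))
      Si <- chol2inv(ch)
      G <- Si - Si %*% C %*% Si       # d loss / d Sigma
      c(as.vector(2 * G %*% Lp), diag(G) * pp)
    }
    # L-BFGS-B with a tight projected-gradient tolerance: the stationarity
    # identity diag(Sigma) = diag(C) is only as exact as the gradient norm
    op <- tryCatch(
      stats::optim(par0, fn, gr, method = "L-BFGS-B",
                   control = list(maxit = 2000, factr = 10, pgtol = 1e-10)),
      error = function(e) NULL)
    if (!is.null(op) && is.finite(op$value) && op$value <= loss) {
      L <- matrix(op$par[seq_len(p * m)], p, m)
      psi2 <- pmax(exp(op$par[p * m + seq_len(p)]), floorv)
      loss <- op$value
      trace <- c(trace, loss)
    }
    if (is.null(best) || loss < best$loss) {
      best <- list(L = L, psi2 = psi2, loss = loss, iters = iters,
                   converged = converged, trace = trace)
    }
  }
  new_compfa_fit("LVFA-ML", best$L, best$psi2, NULL, best$loss, best$iters,
                 best$converged, best$trace)
}
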