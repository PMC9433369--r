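# Shared model objects: validated covariance input, covariance-structure
# identities, and the deterministic eigen/SVD conventions used by every
# estimator in the package.

# symmetry / PSD tolerance, relative to trace (matrices here are small, p <= 24)
.compfa_tol <- 1e-10

#' Validate a sample covariance or correlation matrix
#'
#' Wraps a p x p symmetric positive-semidefinite matrix together with the
#' nominal sample size `n` into a `compfa_cov` object consumed by every
#' estimator in the package. The matrix is symmetrized as `(C + t(C)) / 2`
#' before checking, and whether it is in correlation units (unit diagonal)
#' is recorded.
#'
#' @param C square numeric matrix, covariance or correlation units.
#' @param n positive integer nominal sample size; must exceed `ncol(C)`.
#' @return An object of class `compfa_cov`: a list with elements `C`
#'   (symmetrized matrix), `n`, `p`, and `correlation` (logical flag).
#' @examples
#' cv <- compfa_cov(diag(6), n = 100)
#' cv$correlation
#' @export
compfa_cov <- function(C, n) {
  if (inherits(C, "compfa_cov")) {
    return(compfa_cov(C$C, C$n))  # idempotent revalidation
  }
  C <- as.matrix(C)
  if (!is.numeric(C) || nrow(C) != ncol(C)) {
    stop("`C` must be a square numeric matrix", call. = FALSE)
  }
  if (anyNA(C)) stop("`C` contains missing values", call. = FALSE)
  p <- nrow(C)
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n <= p) {
    stop("`n` must be a single integer greater than p = ", p, call. = FALSE)
  }
  tr <- sum(diag(C))
  tol <- .compfa_tol * max(tr, 1)
  asym <- max(abs(C - t(C)))
  if (asym > tol) {
    stop("`C` is asymmetric beyond tolerance (max |C - C'| = ",
         format(asym), ")", call. = FALSE)
  }
  C <- (C + t(C)) / 2
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol) {
    stop("`C` is not positive semidefinite (smallest eigenvalue ",
         format(min(ev)), ")", call. = FALSE)
  }
  structure(
    list(
      C = C,
      n = n,
      p = p,
      correlation = all(abs(diag(C) - 1) <= 1e-8)
    ),
    class = "compfa_cov"
  )
}

#' @export
print.compfa_cov <- function(x, ...) {
  cat(sprintf("<compfa_cov> p = %d, n = %d, %s units\n", x$p, x$n,
              if (x$correlation) "correlation" else "covariance"))
  invisible(x)
}

#' Model-implied covariance matrix
#'
#' Returns the covariance structure of the comprehensive factor model,
#' `Lambda Lambda' + diag(diag_var) + error_cov`: common part plus diagonal
#' specific (or unique) part plus an error scatter. The result is exactly
#' symmetric.
#'
#' @param loadings p x m loading matrix.
#' @param diag_var length-p vector of diagonal variances (specific variances
#'   for the decomposition estimators, unique variances for the latent-variable
#'   ones).
#' @param error_cov p x p error scatter matrix, or `NULL` / 0 when the model
#'   has no separate error part.
#' @return p x p symmetric matrix.
#' @export
implied_cov <- function(loadings, diag_var, error_cov = NULL) {
  loadings <- as.matrix(loadings)
  p <- nrow(loadings)
  if (length(diag_var) != p) {
    stop("`diag_var` must have length nrow(loadings)", call. = FALSE)
  }
  S <- tcrossprod(loadings) + diag(as.numeric(diag_var), p)
  if (!is.null(error_cov) && !identical(error_cov, 0)) {
    error_cov <- as.matrix(error_cov)
    if (!all(dim(error_cov) == p)) {
      stop("`error_cov` must be p x p", call. = FALSE)
    }
    S <- S + error_cov
  }
  (S + t(S)) / 2
}

#' Communalities of a loading matrix
#'
#' The j-th communality is the squared Euclidean norm of row j of the loading
#' matrix: the variance of variable j explained by the common factors. It is
#' invariant under right-multiplication of the loadings by any orthogonal
#' matrix.
#'
#' @param loadings p x m loading matrix.
#' @return length-p numeric vector.
#' @export
communalities <- function(loadings) {
  loadings <- as.matrix(loadings)
  rowSums(loadings^2)
}

# Symmetric eigendecomposition with a fixed deterministic sign convention:
# eigenvalues decreasing, and in each eigenvector the largest-magnitude
# component is made nonnegative (ties broken by the first such index).
compfa_eigen <- function(M) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  V <- e$vectors
  for (k in seq_len(ncol(V))) {
    j <- which.max(abs(V[, k]))
    if (V[j, k] < 0) V[, k] <- -V[, k]
  }
  list(values = e$values, vectors = V)
}

# Symmetric PSD square root (negative round-off eigenvalues clipped to zero).
compfa_sqrtm <- function(M) {
  e <- compfa_eigen(M)
  d <- pmax(e$values, 0)
  e$vectors %*% (sqrt(d) * t(e$vectors))
}

# Fit options shared by the estimators -----------------------------------

#' Fitting options for the factor-analysis estimators
#'
#' @param tol relative convergence tolerance on the loss between iterations.
#' @param max_iter maximum number of iterations.
#' @param n_starts number of starts; starts beyond the first perturb the
#'   initial unique variances using `seed`.
#' @param seed integer seed for the start perturbations.
#' @param variance_floor lower bound applied to unique variances in the
#'   maximum-likelihood fitter.
#' @return A list of class `compfa_options`.
#' @export
compfa_options <- function(tol = 1e-8, max_iter = 5000L, n_starts = 1L,
                           seed = 1L, variance_floor = 1e-6) {
  stopifnot(tol > 0, max_iter >= 1, n_starts >= 1, variance_floor >= 0)
  structure(
    list(tol = tol, max_iter = as.integer(max_iter),
         n_starts = as.integer(n_starts), seed = as.integer(seed),
         variance_floor = variance_floor),
    class = "compfa_options"
  )
}

# Shared constructor for fitted objects.
new_compfa_fit <- function(method, loadings, diag_var, error_cov, loss,
                           iters, converged, trace, extra = list()) {
  out <- c(
    list(
      method = method,
      loadings = loadings,
      diag_var = as.numeric(diag_var),
      error_cov = error_cov,
      loss = loss,
      iters = as.integer(iters),
      converged = converged,
      proper = min(diag_var) >= 0,
      trace = trace
    ),
    extra
  )
  class(out) <- "compfa_fit"
  out
}

#' @export
print.compfa_fit <- function(x, ...) {
  cat(sprintf("<compfa_fit> method = %s, p = %d, m = %d\n",
              x$method, nrow(x$loadings), ncol(x$loadings)))
  cat(sprintf("  loss = %.6g, iterations = %d, converged = %s, proper = %s\n",
              x$loss, x$iters, x$converged, x$proper))
  invisible(x)
}

# CSV interfaces ----------------------------------------------------------

#' Read a covariance matrix from CSV
#'
#' Reads a square numeric table (optional header row of variable names) and
#' validates it via [compfa_cov()]. Missing values are rejected.
#'
#' @param path CSV file path.
#' @param n nominal sample size to attach.
#' @return A `compfa_cov` object; variable names kept as dimnames when present.
#' @export
read_cov_csv <- function(path, n) {
  first <- utils::read.csv(path, header = FALSE, nrows = 1,
                           stringsAsFactors = FALSE)
  has_header <- !all(vapply(first, function(v)
    is.numeric(v) || !is.na(suppressWarnings(as.numeric(v))), logical(1)))
  tab <- utils::read.csv(path, header = has_header)
  M <- as.matrix(tab)
  if (anyNA(M)) stop("covariance CSV contains missing values", call. = FALSE)
  storage.mode(M) <- "double"
  if (has_header) rownames(M) <- colnames(M)
  compfa_cov(M, n)
}

#' Write fitted loadings and variances to CSV
#'
#' Writes two plain-text tables for a fitted model: a loading table
#' (variables x factors) and a variance table with columns `variable`,
#' `diag_var`, and `error_variance` (`NA` for the latent-variable fits, which
#' do not separate an error part).
#'
#' @param fit a `compfa_fit` object.
#' @param loadings_path,variances_path output CSV paths.
#' @return Invisibly, the variance table as a data frame.
#' @export
write_fit_csv <- function(fit, loadings_path, variances_path) {
  L <- fit$loadings
  p <- nrow(L)
  vars <- rownames(L)
  if (is.null(vars)) vars <- paste0("V", seq_len(p))
  ldf <- data.frame(variable = vars, L, check.names = FALSE)
  colnames(ldf)[-1] <- paste0("F", seq_len(ncol(L)))
  utils::write.csv(ldf, loadings_path, row.names = FALSE)
  ev <- if (is.null(fit$error_cov)) rep(NA_real_, p) else diag(fit$error_cov)
  vdf <- data.frame(variable = vars, diag_var = fit$diag_var,
                    error_variance = ev)
  utils::write.csv(vdf, variances_path, row.names = FALSE)
  invisible(vdf)
}
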