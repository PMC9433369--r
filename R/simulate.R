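# Synthetic covariance generator for the comprehensive factor model. One
# truth draw fixes the loadings, specific variances, and an error-covariance
# scaffold; covariance matrices are then realized at three error-correlation
# levels (none / low / high), two error magnitudes (low / high), and two model
# versions (nonrandom: exact structure plus a realized error scatter; random:
# factor scores drawn as well).

#' Draw generating loadings and specific variances
#'
#' Loadings are i.i.d. uniform on \[-1, 1\] (redrawn until numerical rank m);
#' specific variances are i.i.d. uniform on \[0.1, 0.8\].
#'
#' @param p,m dimensions, `p > m >= 1`.
#' @return A list of class `compfa_truth` with `loadings` (p x m) and
#'   `theta2` (length p).
#' @export
draw_truth <- function(p, m) {
  stopifnot(p > m, m >= 1)
  for (try in 1:100) {
    L <- matrix(stats::runif(p * m, -1, 1), p, m)
    if (min(svd(L, nu = 0, nv = 0)$d) > 1e-8) {
      theta2 <- stats::runif(p, 0.1, 0.8)
      return(structure(list(loadings = L, theta2 = theta2, p = p, m = m),
                       class = "compfa_truth"))
    }
  }
  stop("could not draw a rank-m loading matrix in 100 attempts", call. = FALSE)
}

#' Build the pre-scaling error covariance scaffold
#'
#' At correlation level `"CN"` the scaffold is the diagonal matrix `D_R` with
#' entries uniform on \[0.1, 0.8\]. At `"CL"` and `"CH"` it is
#' `D_R^{1/2} R D_R^{1/2}` where `R` has unit diagonal and off-diagonal
#' entries `tau_jk * r_jk`, with `tau_jk` independent random signs and `r_jk`
#' normal with mean `0.2 * rho` and standard deviation `0.05 * rho` truncated
#' to (-1, 1); `rho` is 1 for `"CL"` and 2 for `"CH"`. A matrix with
#' incoherently signed off-diagonals of magnitude `0.2 * rho` is almost never
#' positive semidefinite at p = 12 (at the high level its expected smallest
#' eigenvalue is about -1.2), so an indefinite draw is replaced by its nearest
#' correlation matrix (alternating projections onto the positive-semidefinite
#' cone and the unit-diagonal set, via [Matrix::nearPD()]). The projection
#' necessarily attenuates the realized correlations (mean magnitude ~0.28 at
#' the high level, ~0.20 at the low level) while preserving their incoherent
#' sign pattern; no positive-semidefinite matrix of this dimension can carry
#' incoherent correlations of mean magnitude 0.4.
#'
#' @param p dimension.
#' @param corr_level one of `"CN"`, `"CL"`, `"CH"`.
#' @param d_r optional pre-drawn diagonal of `D_R` (shared across levels
#'   within a replication); drawn here when `NULL`.
#' @return p x p symmetric positive-semidefinite matrix.
#' @export
build_error_cov <- function(p, corr_level = c("CN", "CL", "CH"), d_r = NULL) {
  corr_level <- match.arg(corr_level)
  if (is.null(d_r)) d_r <- stats::runif(p, 0.1, 0.8)
  if (corr_level == "CN") return(diag(d_r, p))
  rho <- if (corr_level == "CL") 1 else 2
  R <- diag(p)
  for (j in seq_len(p - 1)) {
    for (k in (j + 1):p) {
      repeat {
        r <- stats::rnorm(1, 0.2 * rho, 0.05 * rho)
        if (abs(r) < 1) break   # truncate by resampling the single entry
      }
      tau <- sample(c(-1, 1), 1)
      R[j, k] <- R[k, j] <- tau * r
    }
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 0) {   # replace by the nearest correlation matrix
    R <- Matrix::nearPD(R, corr = TRUE, base.matrix = TRUE)$mat
  }
  s <- sqrt(d_r)
  Phi <- diag(s, p) %*% R %*% diag(s, p)
  (Phi + t(Phi)) / 2
}

#' Error scale factor for a target error-to-common variance ratio
#'
#' Returns `alpha` such that the effective error covariance `alpha^2 * Phi`
#' satisfies `tr(alpha^2 Phi) / tr(Lambda Lambda') = 0.1` (low) or `0.2`
#' (high). With `convention = "literal"` the ratio is instead read as
#' `tr(Phi) / tr(Lambda Lambda')`, in which case the scaffold itself would be
#' rescaled and `sqrt(ratio * tr(LL') / tr(Phi))` is still what is returned -
#' the two conventions coincide in the returned multiplier; the distinction
#' only matters if `Phi` is reported unscaled.
#'
#' @param phi error covariance scaffold.
#' @param loadings generating loading matrix.
#' @param error_level `"EL"` (ratio 0.1) or `"EH"` (ratio 0.2).
#' @param convention `"effective"` (default) or `"literal"`.
#' @return positive scalar `alpha`.
#' @export
scale_errors <- function(phi, loadings, error_level = c("EL", "EH"),
                         convention = c("effective", "literal")) {
  error_level <- match.arg(error_level)
  convention <- match.arg(convention)
  ratio <- if (error_level == "EL") 0.1 else 0.2
  tr_common <- sum(loadings^2)
  if (tr_common <= 0) stop("zero loadings", call. = FALSE)
  tr_phi <- sum(diag(phi))
  if (tr_phi <= 0) stop("`phi` must have positive trace", call. = FALSE)
  sqrt(ratio * tr_common / tr_phi)
}

new_simulated_cov <- function(C, n, truth, cee) {
  structure(
    list(cov = compfa_cov(C, n), truth = truth,
         cee_true = cee, dee_true = diag(cee)),
    class = "compfa_simcov"
  )
}

#' @export
print.compfa_simcov <- function(x, ...) {
  cat(sprintf("<compfa_simcov> p = %d, m = %d, n = %d\n",
              x$truth$p, x$truth$m, x$cov$n))
  invisible(x)
}

#' Nonrandom-version simulated covariance
#'
#' Builds `C = Lambda Lambda' + diag(theta2) + Cee` exactly, where `Cee` is
#' the realized scatter of `n` error draws `alpha * eps_i`,
#' `eps_i ~ N(0, Phi)`. Redraws the errors if the result is rank-deficient.
#'
#' @param truth a `compfa_truth`.
#' @param n sample size, `n > p`.
#' @param phi error covariance scaffold from [build_error_cov()].
#' @param alpha error scale from [scale_errors()].
#' @return A `compfa_simcov`: validated covariance plus the generating truth,
#'   realized error scatter `cee_true`, and its diagonal `dee_true`.
#' @export
gen_cov_nonrandom <- function(truth, n, phi, alpha) {
  p <- truth$p
  stopifnot(n > p)
  base <- tcrossprod(truth$loadings) + diag(truth$theta2, p)
  Phalf <- alpha * compfa_sqrtm(phi)
  for (try in 1:100) {
    Ey <- matrix(stats::rnorm(n * p), n, p) %*% Phalf
    cee <- crossprod(Ey) / n
    C <- base + cee
    ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) > 1e-10 * sum(diag(C))) {
      return(new_simulated_cov(C, n, truth, cee))
    }
  }
  stop("persistent rank deficiency in simulated covariance", call. = FALSE)
}

#' Random-version simulated covariance
#'
#' Draws factor scores `[f_i; s_i] ~ N(0, I)` and errors `alpha * eps_i`, and
#' returns the raw second-moment matrix of `x_i = Lambda f_i +
#' diag(sqrt(theta2)) s_i + e_i`. Unlike the nonrandom version, the common and
#' specific parts are realized too, so `C` fluctuates around the model
#' structure.
#'
#' @inheritParams gen_cov_nonrandom
#' @return A `compfa_simcov`; `cee_true` is the realized error scatter.
#' @export
gen_cov_random <- function(truth, n, phi, alpha) {
  p <- truth$p
  m <- truth$m
  stopifnot(n > p)
  Phalf <- alpha * compfa_sqrtm(phi)
  Th <- diag(sqrt(truth$theta2), p)
  for (try in 1:100) {
    Fm <- matrix(stats::rnorm(n * m), n, m)
    S <- matrix(stats::rnorm(n * p), n, p)
    Ey <- matrix(stats::rnorm(n * p), n, p) %*% Phalf
    X <- Fm %*% t(truth$loadings) + S %*% Th + Ey
    C <- crossprod(X) / n
    ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) > 1e-10 * sum(diag(C))) {
      return(new_simulated_cov(C, n, truth, crossprod(Ey) / n))
    }
  }
  stop("persistent rank deficiency in simulated covariance", call. = FALSE)
}

#' Strong-condition covariance (diagonal realized error scatter)
#'
#' Builds `C = Lambda Lambda' + diag(theta2) + diag(dee)` exactly. Data of
#' this form satisfy the strong uncorrelated-error condition, under which all
#' estimators in the package fit perfectly and their diagonal-variance
#' estimates equal `theta2 + dee`.
#'
#' @param truth a `compfa_truth`.
#' @param dee nonnegative length-p vector of realized error variances.
#' @param n nominal sample size.
#' @return A `compfa_simcov` with `cee_true = diag(dee)`.
#' @export
gen_strong_condition_cov <- function(truth, dee, n = 10L * truth$p) {
  p <- truth$p
  stopifnot(length(dee) == p, all(dee >= 0))
  C <- tcrossprod(truth$loadings) + diag(truth$theta2 + dee, p)
  new_simulated_cov(C, n, truth, diag(dee, p))
}
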