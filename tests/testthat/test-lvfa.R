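# Least-squares and maximum-likelihood latent-variable fits.

test_that("identity covariance decomposes exactly", {
  # every split lambda^2 + psi2 = 1 with a single loaded variable is an exact
  # minimum; assert exactness of the decomposition, not one representative
  cv <- compfa_cov(diag(8), n = 100)
  fit <- fit_lvfa_ls(cv, 1)
  expect_lt(fit$loss, 1e-15)
  expect_equal(communalities(fit$loadings) + fit$diag_var, rep(1, 8),
               tolerance = 1e-8)
})

test_that("one-factor closed form is recovered at p = 3 (just-identified case)", {
  # with all off-diagonals positive the unique one-factor solution is
  # lambda_1 = sqrt(c12 c13 / c23) and cyclically for the others
  lam <- c(0.9, 0.7, 0.5)
  psi2 <- c(0.3, 0.5, 0.6)
  C <- one_factor_cov(lam, psi2)
  lam_cf <- c(
    sqrt(C[1, 2] * C[1, 3] / C[2, 3]),
    sqrt(C[1, 2] * C[2, 3] / C[1, 3]),
    sqrt(C[1, 3] * C[2, 3] / C[1, 2])
  )
  expect_equal(lam_cf, lam, tolerance = 1e-12)  # oracle self-check
  for (fitter in list(fit_lvfa_ls, fit_lvfa_ml)) {
    fit <- fitter(compfa_cov(C, 50), 1)
    expect_lt(fit$loss, 1e-10)
    expect_equal(abs(as.vector(fit$loadings)), lam_cf, tolerance = 1e-5)
    expect_equal(fit$diag_var, psi2, tolerance = 1e-5)
  }
})

test_that("strong-condition covariance is fitted exactly with psi2 = theta2 + dee", {
  set.seed(21)
  tr <- draw_truth(10, 2)
  dee <- runif(10, 0.02, 0.1)
  sim <- gen_strong_condition_cov(tr, dee, n = 100)
  for (fitter in list(fit_lvfa_ls, fit_lvfa_ml)) {
    fit <- fitter(sim$cov, 2)
    expect_lt(fit$loss, 1e-8)
    expect_equal(fit$diag_var, tr$theta2 + dee, tolerance = 1e-4)
    expect_equal(tcrossprod(fit$loadings), tcrossprod(tr$loadings),
                 tolerance = 1e-4)
  }
})

test_that("losses are non-increasing along the iteration trace", {
  set.seed(33)
  for (i in 1:3) {
    C <- rand_psd(7)
    for (fitter in list(fit_lvfa_ls, fit_lvfa_ml)) {
      fit <- fitter(compfa_cov(C, 60), 2)
      expect_true(all(diff(fit$trace) <= 1e-10))
    }
  }
})

test_that("stationarity holds at convergence: diag residual vanishes", {
  set.seed(17)
  C <- rand_psd(8)
  for (fitter in list(fit_lvfa_ls, fit_lvfa_ml)) {
    fit <- fitter(compfa_cov(C, 80), 2)
    resid <- diag(C - tcrossprod(fit$loadings)) - fit$diag_var
    expect_lt(max(abs(resid)), 1e-6)
  }
})

test_that("improper least-squares solutions are flagged, not masked", {
  # just-identified one-factor case with c12*c13 > c23: the exact solution
  # has lambda_1^2 = c12*c13/c23 > 1, hence a negative unique variance
  C <- diag(3)
  C[1, 2] <- C[2, 1] <- 0.7
  C[1, 3] <- C[3, 1] <- 0.7
  C[2, 3] <- C[3, 2] <- 0.3
  fit <- fit_lvfa_ls(compfa_cov(C, 50), 1)
  expect_false(fit$proper)
  expect_true(any(fit$diag_var < 0))
})

test_that("maximum-likelihood loss matches a generic multi-start optimizer", {
  set.seed(51)
  C <- rand_psd(6)
  cv <- compfa_cov(C, 100)
  m <- 1
  fit <- fit_lvfa_ml(cv, m, compfa_options(n_starts = 3))

  # independent oracle: direct numerical minimization of the discrepancy
  # over (loadings, log psi2), many random starts
  nll <- function(par) {
    L <- matrix(par[1:6], 6, m)
    psi2 <- exp(par[7:12])
    S <- tcrossprod(L) + diag(psi2)
    ch <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(ch)) return(1e6)
    Si <- chol2inv(ch)
    M <- C %*% Si
    v <- sum(diag(M)) - determinant(M)$modulus - 6
    if (!is.finite(v)) 1e6 else as.numeric(v)
  }
  best <- Inf
  for (s in 1:25) {
    p0 <- c(rnorm(6, 0, 0.5), log(runif(6, 0.2, 1) * diag(C)))
    o <- optim(p0, nll, method = "BFGS", control = list(maxit = 500))
    best <- min(best, o$value)
  }
  expect_equal(fit$loss, best, tolerance = 1e-6)
})

test_that("ml fit agrees with factanal on a correlation matrix", {
  set.seed(61)
  L0 <- matrix(runif(8 * 2, -0.7, 0.7), 8, 2)
  R <- cov2cor(tcrossprod(L0) + diag(runif(8, 0.4, 1)))
  fit <- fit_lvfa_ml(compfa_cov(R, 200), 2, compfa_options(n_starts = 3))
  fa <- stats::factanal(covmat = R, factors = 2, n.obs = 200,
                        rotation = "none")
  expect_equal(fit$diag_var, unname(fa$uniquenesses), tolerance = 1e-3)
  expect_equal(tcrossprod(fit$loadings),
               tcrossprod(matrix(as.numeric(fa$loadings), 8, 2)),
               tolerance = 1e-3)
})

test_that("refitting after an orthogonal rotation of the start reproduces the loss", {
  set.seed(71)
  C <- rand_psd(6)
  cv <- compfa_cov(C, 60)
  f1 <- fit_lvfa_ls(cv, 2)
  f2 <- fit_lvfa_ls(cv, 2)  # deterministic start: same path
  expect_equal(f1$loss, f2$loss)
  # loss depends on loadings only through their outer product
  Tm <- rand_orthogonal(2)
  expect_equal(compfa:::ls_loss(C, f1$loadings, f1$diag_var),
               compfa:::ls_loss(C, f1$loadings %*% Tm, f1$diag_var),
               tolerance = 1e-12)
})
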