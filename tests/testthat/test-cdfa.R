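# Minimum-rank step and completely decomposed factor analysis.

test_that("exact minimum-rank structure gives objective zero and true theta2", {
  set.seed(61)
  tr <- draw_truth(9, 2)
  C <- tcrossprod(tr$loadings) + diag(tr$theta2, 9)
  mr <- fit_mrfa(compfa_cov(C, 100), 2)
  expect_lt(mr$objective, 1e-7)
  expect_equal(mr$theta2, tr$theta2, tolerance = 1e-4)
  # reduced matrix stays PSD
  expect_gt(min(mr$reduced_eigs), -1e-8)
})

test_that("minimum-rank objective matches an exhaustive grid oracle at p = 3", {
  set.seed(63)
  for (trial in 1:3) {
    C <- rand_psd(3)
    mr <- fit_mrfa(compfa_cov(C, 30), 1)

    # coarse-to-fine grid search over theta2 in [0, diag(C)]^3; at each
    # stage only feasible (PSD-reduced) points are scored
    grid_best <- function(lo, hi, steps) {
      gs <- lapply(1:3, function(j) seq(lo[j], hi[j], length.out = steps))
      best <- Inf
      arg <- NULL
      for (t1 in gs[[1]]) for (t2 in gs[[2]]) for (t3 in gs[[3]]) {
        d <- eigen(C - diag(c(t1, t2, t3)), symmetric = TRUE,
                   only.values = TRUE)$values
        if (d[3] >= -1e-9 && d[2] + d[3] < best) {
          best <- d[2] + d[3]
          arg <- c(t1, t2, t3)
        }
      }
      list(best = best, arg = arg)
    }
    step1 <- diag(C) / 40
    g1 <- grid_best(rep(0, 3), diag(C), 41)
    g2 <- grid_best(pmax(g1$arg - 2 * step1, 0),
                    pmin(g1$arg + 2 * step1, diag(C)), 81)
    step2 <- 4 * step1 / 80
    g3 <- grid_best(pmax(g2$arg - 2 * step2, 0),
                    pmin(g2$arg + 2 * step2, diag(C)), 81)
    expect_lt(abs(mr$objective - g3$best), 1e-4)
  }
})

test_that("cdfa recovers error-free and strong-condition structures exactly", {
  set.seed(65)
  tr <- draw_truth(10, 3)
  C0 <- tcrossprod(tr$loadings) + diag(tr$theta2, 10)
  f0 <- fit_cdfa(compfa_cov(C0, 120), 3)
  expect_lt(f0$loss, 1e-7)
  expect_equal(f0$diag_var, tr$theta2, tolerance = 1e-4)
  expect_equal(tcrossprod(f0$loadings), tcrossprod(tr$loadings),
               tolerance = 1e-4)

  dee <- runif(10, 0.03, 0.12)
  sim <- gen_strong_condition_cov(tr, dee, n = 120)
  f1 <- fit_cdfa(sim$cov, 3)
  expect_lt(f1$loss, 1e-7)
  expect_equal(f1$diag_var, tr$theta2 + dee, tolerance = 1e-4)
})

test_that("cdfa specific variances beat mdfa's on correlated-error data", {
  set.seed(67)
  wins <- 0
  reps <- 15
  for (i in 1:reps) {
    tr <- draw_truth(12, 3)
    phi <- build_error_cov(12, "CH")
    alpha <- scale_errors(phi, tr$loadings, "EH")
    sim <- gen_cov_nonrandom(tr, 200, phi, alpha)
    cd <- fit_cdfa(sim$cov, 3)
    md <- fit_mdfa(sim$cov, 3)
    if (mad_diag(cd$diag_var, tr$theta2) <
        mad_diag(md$diag_var, tr$theta2)) wins <- wins + 1
  }
  expect_gte(wins / reps, 0.9)
})

test_that("reconstructed scores satisfy every orthogonality constraint", {
  set.seed(69)
  tr <- draw_truth(8, 2)
  phi <- build_error_cov(8, "CL")
  alpha <- scale_errors(phi, tr$loadings, "EL")
  sim <- gen_cov_nonrandom(tr, 100, phi, alpha)
  fit <- fit_cdfa(sim$cov, 2)
  sc <- reconstruct_scores(sim$cov, fit)
  n <- 100
  expect_equal(crossprod(sc$X) / n, sim$cov$C, tolerance = 1e-8)
  expect_equal(crossprod(sc$F) / n, diag(2), tolerance = 1e-6)
  expect_equal(crossprod(sc$S) / n, diag(8), tolerance = 1e-6)
  expect_lt(max(abs(crossprod(sc$F, sc$S))), 1e-6 * n)
  expect_lt(max(abs(crossprod(sc$F, sc$E))), 1e-6 * n)
  expect_lt(max(abs(crossprod(sc$S, sc$E))), 1e-6 * n)
  # cross-covariance identities at the solution
  expect_equal(crossprod(sc$X, sc$F) / n, fit$loadings, tolerance = 1e-6)
  expect_equal(crossprod(sc$X, sc$S) / n,
               diag(sqrt(fit$diag_var), 8), tolerance = 1e-6)
  # the same input through the mdfa score system leaves off-diagonal S'E nonzero
  md <- fit_mdfa(sim$cov, 2)
  dd <- mdfa_diagnostics(md)
  expect_gt(dd$max_offdiag_StE, 1e-4)
})

test_that("variance decomposition identity holds exactly for cdfa", {
  set.seed(71)
  tr <- draw_truth(9, 2)
  phi <- build_error_cov(9, "CH")
  alpha <- scale_errors(phi, tr$loadings, "EH")
  sim <- gen_cov_nonrandom(tr, 120, phi, alpha)
  fit <- fit_cdfa(sim$cov, 2)
  vd <- variance_decomposition(fit, sim$cov)
  expect_equal(vd$total, vd$observed, tolerance = 1e-8)
})

test_that("mrfa objective dominance sanity checks hold", {
  set.seed(73)
  C <- rand_psd(8)
  cv <- compfa_cov(C, 90)
  mr <- fit_mrfa(cv, 2)
  obj_at <- function(t2) compfa:::mrfa_objective(C, t2, 2)
  expect_lte(mr$objective, obj_at(rep(0, 8)) + 1e-10)
  ls <- fit_lvfa_ls(cv, 2)
  t2_ls <- pmax(pmin(ls$diag_var, diag(C)), 0)
  d <- eigen(C - diag(t2_ls), symmetric = TRUE, only.values = TRUE)$values
  if (min(d) >= 0) expect_lte(mr$objective, obj_at(t2_ls) + 1e-8)
})
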