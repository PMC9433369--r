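# Synthetic covariance generator.

test_that("truth draws respect the stated ranges and rank condition", {
  set.seed(101)
  tr <- draw_truth(12, 3)
  expect_true(all(abs(tr$loadings) <= 1))
  expect_true(all(tr$theta2 >= 0.1 & tr$theta2 <= 0.8))
  expect_equal(qr(tr$loadings)$rank, 3)
  # degenerate edge: a single column can never be all-zero
  tr2 <- draw_truth(2, 1)
  expect_gt(max(abs(tr2$loadings)), 0)
})

test_that("loading draws have uniform moments", {
  set.seed(103)
  vals <- replicate(400, draw_truth(6, 2)$loadings)
  n <- length(vals)
  se_mean <- sqrt(1 / 3 / n)
  expect_lt(abs(mean(vals)), 3 * se_mean)
  expect_lt(abs(mean(vals^2) - 1 / 3), 3 * sqrt(4 / 45 / n))
})

test_that("error scaffold honors the correlation levels", {
  set.seed(105)
  phi_n <- build_error_cov(12, "CN")
  expect_true(all(phi_n[upper.tri(phi_n)] == 0))
  expect_true(all(diag(phi_n) >= 0.1 & diag(phi_n) <= 0.8))

  for (lvl in c("CL", "CH")) {
    phi <- build_error_cov(12, lvl)
    expect_equal(phi, t(phi), tolerance = 1e-12)
    ev <- eigen(phi, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-8)
  }
  # the high level carries visibly stronger correlations than the low level
  m_abs <- function(lvl) {
    R <- cov2cor(build_error_cov(12, lvl))
    mean(abs(R[upper.tri(R)]))
  }
  ml <- mean(replicate(10, m_abs("CL")))
  mh <- mean(replicate(10, m_abs("CH")))
  expect_gt(mh, ml)
  expect_gt(ml, 0.1)
})

test_that("error scaling hits the requested variance ratio", {
  set.seed(107)
  tr <- draw_truth(10, 2)
  phi <- build_error_cov(10, "CN")
  for (lvl in c("EL", "EH")) {
    a <- scale_errors(phi, tr$loadings, lvl)
    target <- if (lvl == "EL") 0.1 else 0.2
    expect_equal(a^2 * sum(diag(phi)) / sum(tr$loadings^2), target,
                 tolerance = 1e-12)
  }
  # doubling the scaffold halves alpha^2; the high level is sqrt(2) times the low
  a1 <- scale_errors(phi, tr$loadings, "EL")
  a2 <- scale_errors(2 * phi, tr$loadings, "EL")
  expect_equal(a2^2, a1^2 / 2, tolerance = 1e-12)
  expect_equal(scale_errors(phi, tr$loadings, "EH"), sqrt(2) * a1,
               tolerance = 1e-12)
})

test_that("nonrandom version reproduces its construction identity bit for bit", {
  set.seed(109)
  tr <- draw_truth(10, 2)
  phi <- build_error_cov(10, "CL")
  a <- scale_errors(phi, tr$loadings, "EL")
  sim <- gen_cov_nonrandom(tr, 50, phi, a)
  base <- tcrossprod(tr$loadings) + diag(tr$theta2, 10)
  expect_equal(sim$cov$C - base, sim$cee_true, tolerance = 1e-13)
  expect_identical(sim$dee_true, diag(sim$cee_true))
  expect_equal(implied_cov(tr$loadings, tr$theta2, sim$cee_true), sim$cov$C,
               tolerance = 1e-12)
  # alpha = 0 collapses to the exact structure
  sim0 <- gen_cov_nonrandom(tr, 50, phi, 0)
  expect_equal(sim0$cov$C, base, tolerance = 1e-12)
  expect_equal(sim0$dee_true, rep(0, 10))
})

test_that("realized error mass matches the requested ratio on average", {
  set.seed(111)
  tr <- draw_truth(8, 2)
  phi <- build_error_cov(8, "CN")
  a <- scale_errors(phi, tr$loadings, "EL")
  ratios <- replicate(200, {
    s <- gen_cov_nonrandom(tr, 60, phi, a)
    sum(diag(s$cee_true)) / sum(tr$loadings^2)
  })
  # chi-square mean is exact; 3 standard errors of the Monte-Carlo mean
  se <- sd(ratios) / sqrt(length(ratios))
  expect_lt(abs(mean(ratios) - 0.1), 3 * se + 1e-3)
})

test_that("random version converges to the model covariance for large n", {
  set.seed(113)
  tr <- draw_truth(6, 2)
  phi <- build_error_cov(6, "CL")
  a <- scale_errors(phi, tr$loadings, "EH")
  sim <- gen_cov_random(tr, 1e5, phi, a)
  pop <- tcrossprod(tr$loadings) + diag(tr$theta2, 6) + a^2 * phi
  expect_lt(max(abs(sim$cov$C - pop)), 0.02)
  ev <- eigen(sim$cov$C, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
})

test_that("generated covariances validate at full rank and are seed-deterministic", {
  set.seed(115)
  tr <- draw_truth(12, 3)
  phi <- build_error_cov(12, "CH")
  a <- scale_errors(phi, tr$loadings, "EH")
  for (gen in list(gen_cov_nonrandom, gen_cov_random)) {
    set.seed(999)
    s1 <- gen(tr, 200, phi, a)
    set.seed(999)
    s2 <- gen(tr, 200, phi, a)
    expect_identical(s1$cov$C, s2$cov$C)
    expect_equal(qr(s1$cov$C)$rank, 12)
  }
})
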