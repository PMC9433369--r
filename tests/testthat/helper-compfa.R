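# Shared fixtures: small random PSD matrices and orthogonal transforms, all
# built in code at test time.

rand_psd <- function(p, seed = NULL, jitter = 0.3) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(stats::rnorm(p * p), p)
  C <- crossprod(A) / p + diag(jitter, p)
  (C + t(C)) / 2
}

rand_orthogonal <- function(m, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  qr.Q(qr(matrix(stats::rnorm(m * m), m)))
}

# Exact one-factor structure C = ll' + diag(psi2), handy for recovery checks.
one_factor_cov <- function(lambda, psi2) {
  tcrossprod(lambda) + diag(psi2, length(lambda))
}
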