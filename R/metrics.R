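# Recovery metrics: mean absolute differences between estimated and
# generating parameters (loadings after Procrustes alignment), the Delta
# contrast between the latent-variable and matrix-decomposition specific
# variance errors, and the per-variable variance decomposition.

#' Mean absolute difference between loading matrices
#'
#' `||estimate - truth||_1 / (p * m)`. The estimate should already be
#' Procrustes-aligned to the truth (set `align = TRUE` to do it here), since
#' loadings are only identified up to an orthogonal transform.
#'
#' @param estimate,truth p x m matrices.
#' @param align align `estimate` to `truth` first.
#' @return nonnegative scalar.
#' @export
mad_loadings <- function(estimate, truth, align = FALSE) {
  estimate <- as.matrix(estimate)
  truth <- as.matrix(truth)
  if (!all(dim(estimate) == dim(truth))) {
    stop("`estimate` and `truth` must have the same shape", call. = FALSE)
  }
  if (align) estimate <- procrustes_align(estimate, truth)$rotated
  mean(abs(estimate - truth))
}

#' Mean absolute difference between diagonal-variance vectors
#'
#' `||est - ref||_1 / p`. The caller supplies the appropriate pair: unique
#' variances (latent-variable fits) or specific variances (decomposition
#' fits) against either the generating specific variances or their sum with
#' the realized error variances.
#'
#' @param est_diag,ref_diag length-p vectors.
#' @return nonnegative scalar.
#' @export
mad_diag <- function(est_diag, ref_diag) {
  if (length(est_diag) != length(ref_diag)) {
    stop("length mismatch", call. = FALSE)
  }
  mean(abs(est_diag - ref_diag))
}

#' Delta contrast between latent-variable and matrix-decomposition recovery
#'
#' `Delta = MAD(theta2) for the latent-variable fit minus MAD(theta2) for the
#' matrix-decomposition fit` on the same covariance; a positive value means
#' the matrix-decomposition specific variances are closer to the generating
#' ones.
#'
#' @param mad_lvfa,mad_mdfa the two specific-variance MAD values.
#' @return scalar difference.
#' @export
delta_stat <- function(mad_lvfa, mad_mdfa) {
  mad_lvfa - mad_mdfa
}

#' Per-variable variance decomposition of a fitted solution
#'
#' Splits each observed variance into a communality, a specific (or unique)
#' variance, and - for the decomposition estimators - an error variance. For
#' those estimators the three parts sum to the observed diagonal exactly; for
#' the latent-variable fits the communality and unique variance alone do, and
#' the error column is `NA` rather than zero because the error part is not
#' separated.
#'
#' @param fit a `compfa_fit`.
#' @param cov the `compfa_cov` it was fitted to.
#' @return A tibble with columns `variable`, `communality`,
#'   `specific_variance`, `error_variance`, `total`.
#' @export
variance_decomposition <- function(fit, cov) {
  stopifnot(inherits(fit, "compfa_fit"))
  cov <- if (inherits(cov, "compfa_cov")) cov else
    compfa_cov(cov, nrow(cov) + 1L)
  p <- cov$p
  vars <- rownames(fit$loadings)
  if (is.null(vars)) vars <- paste0("V", seq_len(p))
  h2 <- communalities(fit$loadings)
  ev <- if (is.null(fit$error_cov)) rep(NA_real_, p) else diag(fit$error_cov)
  tibble::tibble(
    variable = vars,
    communality = h2,
    specific_variance = fit$diag_var,
    error_variance = ev,
    total = h2 + fit$diag_var + dplyr::coalesce(ev, 0),
    observed = diag(cov$C)
  )
}
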