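# Orthogonal rotations: Procrustes alignment of an estimated loading matrix
# to a target (used before recovery metrics, since loadings are only
# identified up to an orthogonal transform), and varimax for interpretation.

#' Orthogonal Procrustes alignment
#'
#' Finds the orthogonal matrix `T` minimizing `||loadings %*% T - target||^2`
#' (reflections allowed, so sign flips and column permutations are repaired
#' automatically), via the SVD of `t(loadings) %*% target`.
#'
#' @param loadings,target p x m matrices of the same shape.
#' @return A list of class `compfa_rotation`: `rotated` (`loadings %*% T`),
#'   `transform` (`T`), and `criterion` (the minimized squared distance).
#' @export
procrustes_align <- function(loadings, target) {
  loadings <- as.matrix(loadings)
  target <- as.matrix(target)
  if (!all(dim(loadings) == dim(target))) {
    stop("`loadings` and `target` must have the same shape", call. = FALSE)
  }
  sv <- svd(crossprod(loadings, target))
  Tm <- sv$u %*% t(sv$v)
  rotated <- loadings %*% Tm
  structure(
    list(rotated = rotated, transform = Tm,
         criterion = sum((rotated - target)^2)),
    class = "compfa_rotation"
  )
}

varimax_criterion <- function(L) {
  sq <- L^2
  sum(apply(sq, 2, function(col) mean(col^2) - mean(col)^2))
}

#' Varimax rotation
#'
#' Orthogonally rotates a loading matrix to maximize the varimax criterion
#' (the summed column variances of squared loadings), with Kaiser row
#' normalization applied during optimization and undone afterward. Columns of
#' the result are sign-fixed (largest-magnitude loading positive) and ordered
#' by decreasing sum of squares, with the permutation and signs folded into
#' the returned orthogonal transform.
#'
#' @param loadings p x m loading matrix; returned unchanged for `m = 1`.
#' @param normalize apply Kaiser row normalization during optimization.
#' @return A `compfa_rotation` list; `criterion` is the varimax criterion of
#'   the returned (unnormalized) matrix.
#' @export
varimax_rotate <- function(loadings, normalize = TRUE) {
  loadings <- as.matrix(loadings)
  m <- ncol(loadings)
  if (m == 1L) {
    return(structure(
      list(rotated = loadings, transform = diag(1),
           criterion = varimax_criterion(loadings)),
      class = "compfa_rotation"
    ))
  }
  vr <- stats::varimax(loadings, normalize = normalize, eps = 1e-10)
  Tm <- vr$rotmat
  R <- loadings %*% Tm
  # deterministic column signs and order
  sgn <- vapply(seq_len(m), function(k) {
    s <- sign(R[which.max(abs(R[, k])), k])
    if (s == 0) 1 else s
  }, numeric(1))
  R <- sweep(R, 2, sgn, `*`)
  Tm <- sweep(Tm, 2, sgn, `*`)
  ord <- order(colSums(R^2), decreasing = TRUE)
  R <- R[, ord, drop = FALSE]
  Tm <- Tm[, ord, drop = FALSE]
  structure(
    list(rotated = R, transform = Tm, criterion = varimax_criterion(R)),
    class = "compfa_rotation"
  )
}

#' @export
print.compfa_rotation <- function(x, ...) {
  cat(sprintf("<compfa_rotation> %d x %d, criterion = %.6g\n",
              nrow(x$rotated), ncol(x$rotated), x$criterion))
  invisible(x)
}
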