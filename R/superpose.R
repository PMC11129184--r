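# Rigid-body (Kabsch) superposition.

#' Optimal rigid superposition of two coordinate sets
#'
#' Kabsch algorithm via SVD of the weighted cross-covariance. Returns the
#' proper rotation (det = +1), translation and minimal weighted RMSD such
#' that `coords %*% t(rotation) + translation` best fits `reference`.
#'
#' @param mobile N x 3 coordinates (Angstrom).
#' @param reference N x 3 coordinates in 1:1 correspondence with `mobile`.
#' @param weights Optional non-negative weights of length N (default uniform).
#' @return List with `rotation` (3 x 3), `translation` (length 3), `rmsd`
#'   (Angstrom, weighted).
#' @export
#' @examples
#' a <- matrix(rnorm(12), 4, 3)
#' superpose_kabsch(a, a)$rmsd
superpose_kabsch <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  n <- nrow(mobile)
  if (n < 3L || nrow(reference) != n || ncol(mobile) != 3L || ncol(reference) != 3L)
    stop("ill-posed superposition: need matching N x 3 sets with N >= 3")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0) || sum(weights) <= 0)
    stop("weights must be non-negative with positive sum")
  w <- weights / sum(weights)
  cm <- colSums(mobile * w); cr <- colSums(reference * w)
  M <- sweep(mobile, 2, cm); R <- sweep(reference, 2, cr)
  # non-collinearity: centered reference must span at least 2 dimensions
  sv_ref <- svd(R * sqrt(w))$d
  if (sv_ref[2] < 1e-9 * max(sv_ref[1], 1e-300))
    stop("ill-posed superposition: reference geometry is (near-)collinear")
  H <- t(M * w) %*% R
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  aligned <- M %*% t(rot)
  rmsd <- sqrt(sum(w * rowSums((aligned - R)^2)))
  list(rotation = rot, translation = as.numeric(cr - as.numeric(rot %*% cm)),
       rmsd = rmsd)
}

#' Apply a rigid transform to coordinates
#'
#' @param coords N x 3 matrix.
#' @param fit Result of [superpose_kabsch()].
#' @return Transformed N x 3 matrix.
#' @export
apply_transform <- function(coords, fit) {
  sweep(as.matrix(coords) %*% t(fit$rotation), 2, fit$translation, "+")
}
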