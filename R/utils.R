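# Shared numeric helpers: seeded RNG scopes, minimum-image distances,
# small linear algebra used across modules.

#' Evaluate code with a temporary RNG seed
#'
#' Sets the Mersenne-Twister seed for the duration of `code` and restores the
#' caller's RNG state afterwards, so generators are bit-reproducible given
#' (spec, seed) without clobbering the session stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

#' Minimum-image displacement
#'
#' Applies the minimum-image convention componentwise for an orthorhombic
#' box. `dx` may be a vector or an n x 3 matrix of raw displacements.
#'
#' @param dx Displacements in Angstrom.
#' @param box Length-3 box edge vector in Angstrom, or NULL for no box.
#' @return Displacements wrapped into (-box/2, box/2].
#' @keywords internal
min_image <- function(dx, box = NULL) {
  if (is.null(box)) return(dx)
  if (is.matrix(dx)) {
    for (k in 1:3) dx[, k] <- dx[, k] - box[k] * round(dx[, k] / box[k])
  } else {
    dx <- dx - box * round(dx / box)
  }
  dx
}

# All pairwise minimum-image distances between rows of a (n x 3) and b (m x 3).
pair_dist_matrix <- function(a, b, box = NULL) {
  n <- nrow(a); m <- nrow(b)
  d2 <- matrix(0, n, m)
  for (k in 1:3) {
    dx <- outer(a[, k], b[, k], "-")
    if (!is.null(box)) dx <- dx - box[k] * round(dx / box[k])
    d2 <- d2 + dx * dx
  }
  sqrt(d2)
}

# Moore-Penrose pseudo-inverse via SVD; used for tiny (3x3) Gram matrices.
pinv <- function(m, tol = 1e-12) {
  s <- svd(m)
  keep <- s$d > tol * max(s$d, 0)
  if (!any(keep)) return(matrix(0, ncol(m), nrow(m)))
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

# Round half away from zero to `digits` decimals (base round() is banker's).
round_half_away <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Uniform unit vectors on the sphere: normalized standard 3D normals.
# Returns 3 x n matrix.
random_unit_vectors <- function(n) {
  v <- matrix(rnorm(3 * n), nrow = 3)
  nrm <- sqrt(colSums(v^2))
  nrm[nrm == 0] <- 1
  sweep(v, 2, nrm, "/")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
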