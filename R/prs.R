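# Perturbation response scanning (PRS).
#
# Linear response theory relates an external force F applied at one CA node
# to the displacement of all nodes through the positional covariance C of
# the fluctuating structure: dR = C F (the thermal 1/kT prefactor is
# dropped -- the overlap score below is invariant to any positive scaling of
# C, F or the target). Each node is scanned with many random force
# directions; the score of a node is the best absolute cosine overlap
# between its predicted displacement field and the target conformational
# change (e.g. the closed-to-open difference between experimental
# structures). Nodes above a significance threshold (default 0.6) are
# reported as candidate allosteric hotspots.

#' Positional covariance of selected nodes from a trajectory
#'
#' Each frame is rigidly superposed (Kabsch, on the selection) to an
#' iteratively refined mean structure: frames are first aligned to frame 1,
#' the mean is computed, frames are re-aligned to that mean, and the mean is
#' recomputed (`iterations` passes, default 2 -- cheap and stable). The
#' covariance uses the frame-count denominator n (population form; the
#' overlap score is invariant to the choice).
#'
#' @param traj A `Trajectory`.
#' @param selection Selection string resolving to the nodes (one atom per
#'   node; typically `"name CA"`).
#' @param align Superpose frames before accumulating (default TRUE). Set
#'   FALSE when frames are already in a common frame of reference.
#' @param iterations Mean-refinement passes when aligning.
#' @return A `CovarianceMatrix`: list with `matrix` (3N x 3N, Angstrom^2),
#'   `nodes` (data.frame chain/resid/resname), `n_frames_used`,
#'   `alignment_reference`.
#' @export
compute_covariance <- function(traj, selection = "name CA", align = TRUE,
                               iterations = 2) {
  stopifnot(inherits(traj, "Trajectory"))
  idx <- select_atoms(traj$topology, selection)
  if (length(idx) < 4L) stop("selection resolves to ", length(idx),
                             " nodes; need >= 4")
  nf <- n_frames(traj)
  if (nf < 2L) stop("insufficient data: need >= 2 frames for a covariance")
  n <- length(idx)
  X <- matrix(0, nf, 3 * n)   # frames x 3N, xyz per node
  for (f in seq_len(nf)) X[f, ] <- as.numeric(t(traj$coords[idx, , f]))
  if (align) {
    ref <- matrix(X[1, ], ncol = 3, byrow = TRUE)
    for (it in seq_len(iterations)) {
      for (f in seq_len(nf)) {
        m <- matrix(X[f, ], ncol = 3, byrow = TRUE)
        fit <- superpose_kabsch(m, ref)
        X[f, ] <- as.numeric(t(apply_transform(m, fit)))
      }
      ref <- matrix(colMeans(X), ncol = 3, byrow = TRUE)
    }
  }
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  C <- crossprod(Xc) / nf
  structure(list(matrix = C,
                 nodes = residue_nodes(traj$topology, idx),
                 n_frames_used = nf,
                 alignment_reference = if (align)
                   sprintf("iterative mean (%d passes) on '%s'",
                           iterations, selection) else "none"),
            class = "CovarianceMatrix")
}

#' @export
print.CovarianceMatrix <- function(x, ...) {
  cat("CovarianceMatrix:", nrow(x$nodes), "nodes (3N =", nrow(x$matrix),
      "), from", x$n_frames_used, "frames; alignment:",
      x$alignment_reference, "\n")
  invisible(x)
}

# Wrap a plain PSD matrix (e.g. a synthetic true covariance) for PRS use.
#' Construct a CovarianceMatrix from a plain 3N x 3N matrix
#' @param m Symmetric PSD 3N x 3N matrix (Angstrom^2).
#' @param nodes Optional data.frame (chain, resid); default chain "A",
#'   resid 1..N.
#' @return A `CovarianceMatrix`.
#' @export
as_covariance <- function(m, nodes = NULL) {
  m <- as.matrix(m)
  n3 <- nrow(m)
  if (ncol(m) != n3 || n3 %% 3L != 0L) stop("matrix must be square 3N x 3N")
  if (max(abs(m - t(m))) > 1e-8 * max(1, max(abs(m))))
    stop("matrix is not symmetric")
  n <- n3 %/% 3L
  if (is.null(nodes))
    nodes <- data.frame(chain = "A", resid = seq_len(n), resname = "ALA",
                        stringsAsFactors = FALSE)
  structure(list(matrix = m, nodes = nodes, n_frames_used = NA_integer_,
                 alignment_reference = "external"),
            class = "CovarianceMatrix")
}

#' Linear-response displacement to a point force
#'
#' dR = C F, with F the 3N embedding of a force at one node (zeros
#' elsewhere).
#'
#' @param C A `CovarianceMatrix`.
#' @param residue_index Node index (1-based into `C$nodes`).
#' @param direction Length-3 force direction (normalized internally).
#' @param magnitude Positive scalar force magnitude (default 1; the overlap
#'   score is invariant to it).
#' @return Numeric 3N displacement vector (class `DisplacementField` via
#'   attribute `nodes`).
#' @export
linear_response <- function(C, residue_index, direction, magnitude = 1) {
  stopifnot(inherits(C, "CovarianceMatrix"))
  n <- nrow(C$nodes)
  if (residue_index < 1 || residue_index > n)
    stop("residue_index ", residue_index, " out of range 1..", n)
  d <- as.numeric(direction)
  nrm <- sqrt(sum(d^2))
  if (nrm == 0) stop("zero force direction")
  cols <- (3 * residue_index - 2):(3 * residue_index)
  dr <- as.numeric(C$matrix[, cols] %*% (magnitude * d / nrm))
  attr(dr, "nodes") <- C$nodes
  dr
}

#' Overlap between a response and a target displacement
#'
#' O = |dR . dS| / (|dR| |dS|), in [0, 1]. The absolute value is taken
#' because the force sign is arbitrary (a force and its negation probe the
#' same direction). Returns 0 for a zero response.
#'
#' @param dR Predicted 3N displacement.
#' @param dS Target 3N displacement (must be non-zero).
#' @return Overlap in [0, 1].
#' @export
overlap <- function(dR, dS) {
  dR <- as.numeric(dR); dS <- as.numeric(dS)
  if (length(dR) != length(dS))
    stop("displacement fields have different node sets (",
         length(dR), " vs ", length(dS), " coordinates)")
  ns <- sqrt(sum(dS^2))
  if (ns == 0) stop("target displacement has zero norm")
  nr <- sqrt(sum(dR^2))
  if (nr == 0) return(0)
  abs(sum(dR * dS)) / (nr * ns)
}

#' Closed-form optimal force direction at one node
#'
#' With `B` the 3 x 3 Gram matrix of the node's covariance columns and
#' `a` their projection on the target, the unit force maximizing the
#' absolute cosine overlap is proportional to `solve(B, a)` (pseudo-inverse
#' when B is singular). Serves as the analytic oracle for the random scan.
#'
#' @param C A `CovarianceMatrix`.
#' @param node_index Node index (1-based).
#' @param dS Target 3N displacement.
#' @return List with `direction` (unit 3-vector), `overlap`, and
#'   `degenerate` (TRUE when the node cannot respond toward the target).
#' @export
analytic_best_force <- function(C, node_index, dS) {
  stopifnot(inherits(C, "CovarianceMatrix"))
  n <- nrow(C$nodes)
  if (node_index < 1 || node_index > n)
    stop("node_index ", node_index, " out of range 1..", n)
  dS <- as.numeric(dS)
  cols <- (3 * node_index - 2):(3 * node_index)
  Cb <- C$matrix[, cols, drop = FALSE]          # 3N x 3
  a <- as.numeric(crossprod(Cb, dS))            # 3
  if (sqrt(sum(a^2)) < 1e-14 * max(1, sqrt(sum(dS^2)))) {
    return(list(direction = c(1, 0, 0), overlap = 0, degenerate = TRUE))
  }
  B <- crossprod(Cb)                            # 3 x 3
  f <- tryCatch(solve(B, a), error = function(e) as.numeric(pinv(B) %*% a))
  if (any(!is.finite(f)) || sum(f^2) == 0) f <- as.numeric(pinv(B) %*% a)
  f <- f / sqrt(sum(f^2))
  list(direction = f,
       overlap = overlap(as.numeric(Cb %*% f), dS),
       degenerate = FALSE)
}

#' Random-force perturbation scan over all nodes
#'
#' For every node, samples `n_directions` uniform unit force directions per
#' repeat (`n_repeats` repeats; directions are normalized standard 3D
#' normals from one seeded stream) and records the best overlap achieved
#' and the direction achieving it. `aggregate = "max"` keeps the best over
#' all repeats (default); `"mean"` averages the per-repeat best overlaps
#' (the reported direction is then the overall best).
#'
#' @param C A `CovarianceMatrix`.
#' @param dS Target 3N displacement.
#' @param n_directions Force directions per repeat (default 1000).
#' @param n_repeats Repeats (default 5).
#' @param seed Integer seed for the direction stream.
#' @param threshold Significance threshold stored with the profile
#'   (default 0.6).
#' @param aggregate `"max"` or `"mean"` across repeats.
#' @return An `OverlapProfile`: data.frame with one row per node (chain,
#'   resid, best_overlap, fx, fy, fz) and attributes `n_directions_sampled`,
#'   `threshold`.
#' @export
prs_scan <- function(C, dS, n_directions = 1000, n_repeats = 5, seed = 1,
                     threshold = 0.6, aggregate = c("max", "mean")) {
  stopifnot(inherits(C, "CovarianceMatrix"), n_directions >= 1, n_repeats >= 1)
  aggregate <- match.arg(aggregate)
  dS <- as.numeric(dS)
  if (length(dS) != nrow(C$matrix))
    stop("target displacement length ", length(dS), " != 3N = ", nrow(C$matrix))
  ns <- sqrt(sum(dS^2))
  if (ns == 0) stop("target displacement has zero norm")
  n <- nrow(C$nodes)
  best_ov <- numeric(n); best_dir <- matrix(0, n, 3)
  repeat_best <- matrix(0, n, n_repeats)
  with_seed(seed, {
    for (rep_i in seq_len(n_repeats)) {
      for (i in seq_len(n)) {
        dirs <- random_unit_vectors(n_directions)       # 3 x D
        cols <- (3 * i - 2):(3 * i)
        Rsp <- C$matrix[, cols, drop = FALSE] %*% dirs  # 3N x D
        num <- abs(as.numeric(crossprod(Rsp, dS)))
        den <- sqrt(colSums(Rsp^2)) * ns
        ov <- ifelse(den > 0, num / den, 0)
        k <- which.max(ov)
        repeat_best[i, rep_i] <- ov[k]
        if (ov[k] > best_ov[i]) {
          best_ov[i] <- ov[k]
          best_dir[i, ] <- dirs[, k]
        }
      }
    }
  })
  score <- if (aggregate == "max") best_ov else rowMeans(repeat_best)
  out <- data.frame(chain = C$nodes$chain, resid = C$nodes$resid,
                    best_overlap = score,
                    fx = best_dir[, 1], fy = best_dir[, 2], fz = best_dir[, 3],
                    stringsAsFactors = FALSE)
  attr(out, "n_directions_sampled") <- n_directions * n_repeats
  attr(out, "threshold") <- threshold
  class(out) <- c("OverlapProfile", "data.frame")
  out
}

#' Rank allosteric hotspot candidates from an overlap profile
#'
#' Nodes with best overlap >= `threshold` (inclusive), sorted by overlap
#' descending; ties broken by ascending residue number (then chain).
#'
#' @param profile An `OverlapProfile` from [prs_scan()].
#' @param threshold Significance threshold (default: the profile's stored
#'   threshold, itself defaulting to 0.6).
#' @return data.frame (chain, resid, best_overlap), possibly empty.
#' @export
rank_hotspots <- function(profile, threshold = NULL) {
  threshold <- threshold %||% attr(profile, "threshold") %||% 0.6
  keep <- profile$best_overlap >= threshold
  out <- profile[keep, c("chain", "resid", "best_overlap"), drop = FALSE]
  out <- out[order(-out$best_overlap, out$resid, out$chain), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Target displacement field between two structures
#'
#' Superposes the target onto the initial structure (Kabsch on the
#' selection) and returns the per-node coordinate difference as a 3N
#' vector -- the conformational-change direction that PRS responses are
#' scored against.
#'
#' @param initial A `Structure` (the simulated starting state).
#' @param target A `Structure` (e.g. the experimental endpoint).
#' @param selection Selection string; must resolve to equally many,
#'   correspondingly ordered atoms in both structures.
#' @param superpose Superpose first (default TRUE; disable for pre-aligned
#'   toys).
#' @return Numeric 3N displacement vector with attribute `nodes`.
#' @export
target_displacement <- function(initial, target, selection = "name CA",
                                superpose = TRUE) {
  ii <- select_atoms(initial, selection)
  it <- select_atoms(target, selection)
  if (length(ii) != length(it))
    stop("correspondence error: selection resolves to ", length(ii),
         " atoms in initial but ", length(it), " in target")
  xi <- initial$coords[ii, , drop = FALSE]
  xt <- target$coords[it, , drop = FALSE]
  if (superpose) {
    fit <- superpose_kabsch(xt, xi)
    xt <- apply_transform(xt, fit)
  }
  d <- as.numeric(t(xt - xi))
  attr(d, "nodes") <- residue_nodes(initial, ii)
  d
}

#' First frame of the converged trajectory interval
#'
#' Picks an equilibrated starting frame automatically: the first frame of
#' the longest suffix of the trajectory whose per-frame CA RMSD to the final
#' frame stays below `rmsd_bound` (default 1 Angstrom). PRS assumes a
#' relaxed starting conformation, so covariance accumulation should begin
#' here.
#'
#' @param traj A `Trajectory`.
#' @param selection Node selection (default `"name CA"`).
#' @param rmsd_bound RMSD bound in Angstrom.
#' @return Frame index (1-based).
#' @export
converged_start <- function(traj, selection = "name CA", rmsd_bound = 1) {
  idx <- select_atoms(traj$topology, selection)
  if (length(idx) < 3L) stop("selection too small for RMSD")
  nf <- n_frames(traj)
  ref <- traj$coords[idx, , nf]
  r <- vapply(seq_len(nf), function(f)
    superpose_kabsch(traj$coords[idx, , f], ref)$rmsd, numeric(1))
  below <- r < rmsd_bound
  # longest suffix entirely below the bound
  start <- nf
  for (f in nf:1) {
    if (below[f]) start <- f else break
  }
  start
}
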