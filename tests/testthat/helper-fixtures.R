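# Shared fixture builders (everything is generated in code at test time).

# Minimal PDB text: one CA per residue at given coords.
write_toy_pdb <- function(path, coords, chains = "A", resids = NULL,
                          names = "CA", resnames = "ALA", elements = "C",
                          icode = NULL) {
  n <- nrow(coords)
  chains <- rep_len(chains, n); names <- rep_len(names, n)
  resnames <- rep_len(resnames, n); elements <- rep_len(elements, n)
  if (is.null(resids)) resids <- seq_len(n)
  ic <- if (is.null(icode)) rep(" ", n) else rep_len(icode, n)
  lines <- sprintf(
    "ATOM  %5d  %-3s %-4s%1s%4d%1s   %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    seq_len(n), names, resnames, chains, resids, ic,
    coords[, 1], coords[, 2], coords[, 3], elements)
  writeLines(c(lines, "END"), path)
  path
}

# Structure built directly (no file round-trip).
make_structure <- function(coords, chains = "A", resids = NULL,
                           names = "CA", resnames = "ALA", elements = "C") {
  n <- nrow(coords)
  if (is.null(resids)) resids <- seq_len(n)
  new_structure(
    data.frame(atom_name = rep_len(names, n),
               element = rep_len(elements, n),
               resid = resids,
               resname = rep_len(resnames, n),
               chain = rep_len(chains, n),
               stringsAsFactors = FALSE),
    coords)
}

# A trajectory where one lipid bead follows a prescribed distance-to-residue
# series along x from a single fixed protein bead: used for hand-traced
# hysteresis tests. dt = 1 ns.
distance_series_traj <- function(dists, box = NULL) {
  prot <- make_structure(matrix(c(0, 0, 0), 1, 3), chains = "A")
  nf <- length(dists)
  coords <- lapply(dists, function(d) rbind(c(0, 0, 0), c(d, 0, 0)))
  topo <- new_structure(
    rbind(prot$atoms,
          data.frame(atom_name = "R1", element = "C", resid = 1L,
                     resname = "CHOL", chain = "L", stringsAsFactors = FALSE)),
    coords[[1]])
  new_trajectory(topo, coords, times = seq_len(nf) - 1, box = box)
}

# Random PSD covariance on n nodes (Wishart-style), seeded.
random_psd_covariance <- function(n_nodes, seed) {
  n3 <- 3 * n_nodes
  memallo:::with_seed(seed, {
    A <- matrix(rnorm(n3 * n3), n3, n3)
    as_covariance(crossprod(A) / n3)
  })
}

# Brute-force rotation search RMSD oracle: dense quaternion grid refined
# around the best cell. Independent of the SVD path.
grid_search_rmsd <- function(mobile, reference, n_coarse = 12000, seed = 42) {
  cm <- colMeans(mobile); cr <- colMeans(reference)
  M <- sweep(mobile, 2, cm); R <- sweep(reference, 2, cr)
  rot_from_quat <- function(q) {
    q <- q / sqrt(sum(q^2)); w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
             2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
             2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
           3, 3, byrow = TRUE)
  }
  score <- function(q) {
    A <- M %*% t(rot_from_quat(q))
    sqrt(mean(rowSums((A - R)^2)))
  }
  memallo:::with_seed(seed, {
    Q <- matrix(rnorm(4 * n_coarse), ncol = 4)
    vals <- apply(Q, 1, score)
    best <- Q[which.min(vals), ]
    bestval <- min(vals)
    # local refinement
    step <- 0.1
    for (it in 1:60) {
      cand <- sweep(matrix(rnorm(4 * 200, sd = step), ncol = 4), 2, best, "+")
      cv <- apply(cand, 1, score)
      if (min(cv) < bestval) { bestval <- min(cv); best <- cand[which.min(cv), ] }
      step <- step * 0.85
    }
    bestval
  })
}

# Standard small lipid-walk fixture shared by density/site tests.
walk_fixture <- function(seed = 1, n_lipids = 50, n_frames = 2000,
                         mean_dwell = 50, diffusion_step = 6, r_bind = 3,
                         box = c(60, 60, 60)) {
  prot <- toy_protein(box)
  spec <- lipid_kinetics_spec(box, n_lipids, diffusion_step,
                              rbind(box / 2), r_bind, mean_dwell,
                              frame_dt = 1, n_frames = n_frames, seed = seed)
  generate_lipid_walk(spec, prot)
}

# Brute-force occupancy recount: literal per-frame loop over particles.
recount_occupancy <- function(traj, selection, spacing) {
  idx <- select_atoms(traj$topology, selection)
  box <- traj$box[1, ]
  dims <- as.integer(ceiling(box / spacing - 1e-9)); dims[dims < 1] <- 1L
  hit <- array(0, dim = dims)
  nf <- n_frames(traj)
  for (f in seq_len(nf)) {
    seen <- array(FALSE, dim = dims)
    for (i in idx) {
      v <- integer(3)
      for (k in 1:3) {
        xk <- traj$coords[i, k, f] %% box[k]
        v[k] <- min(dims[k] - 1L, floor(xk / spacing))
      }
      seen[v[1] + 1L, v[2] + 1L, v[3] + 1L] <- TRUE
    }
    hit <- hit + seen
  }
  hit / nf
}
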