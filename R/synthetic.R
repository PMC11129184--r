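# Synthetic-data generators.
#
# These produce inputs with exactly the statistical structure the analysis
# stages assume -- a Gaussian fluctuation ensemble with known covariance, a
# coarse-grained lipid random walk with planted binding sites and
# exponential dwell kinetics, and small hydrogen-bond geometry fixtures --
# so every downstream stage can be validated against planted truth without
# microsecond simulation data. All generators are bit-reproducible given
# (spec, seed).

## --- covariance builders --------------------------------------------------

#' Covariance builders for Gaussian ensembles
#'
#' `cov_isotropic(sigma2)` gives sigma2 * I (independent isotropic
#' fluctuations). `cov_spiked(sigma2, lambda, u)` adds one planted soft mode:
#' sigma2 * I + lambda * u u^T with `u` a unit 3N-vector; this is the
#' canonical test bed for hotspot recovery. `cov_enm(cutoff, k)` builds an
#' anisotropic elastic-network covariance as the pseudo-inverse of the ENM
#' Hessian (springs of constant `k` between nodes within `cutoff` Angstrom),
#' giving correlated, structure-dependent fluctuations.
#'
#' @param sigma2 Per-coordinate variance, Angstrom^2.
#' @param lambda Spike variance along `u`, Angstrom^2.
#' @param u Unit 3N-vector (will be checked, not renormalized).
#' @param cutoff ENM spring cutoff, Angstrom.
#' @param k ENM spring constant (inverse-variance units).
#' @return A covariance-builder object for [gaussian_ensemble_spec()].
#' @name covariance_builders
NULL

#' @rdname covariance_builders
#' @export
cov_isotropic <- function(sigma2) {
  stopifnot(sigma2 >= 0)
  structure(list(type = "isotropic", sigma2 = sigma2), class = "cov_builder")
}

#' @rdname covariance_builders
#' @export
cov_spiked <- function(sigma2, lambda, u) {
  stopifnot(sigma2 >= 0, lambda >= 0)
  if (abs(sqrt(sum(u^2)) - 1) > 1e-8)
    stop("spike vector u must have unit norm")
  structure(list(type = "spiked", sigma2 = sigma2, lambda = lambda, u = u),
            class = "cov_builder")
}

#' @rdname covariance_builders
#' @export
cov_enm <- function(cutoff = 10, k = 1) {
  stopifnot(cutoff > 0, k > 0)
  structure(list(type = "enm", cutoff = cutoff, k = k), class = "cov_builder")
}

# Materialize a builder into a 3N x 3N covariance for the given mean coords.
build_covariance_matrix <- function(builder, mean_coords) {
  n3 <- 3L * nrow(mean_coords)
  switch(builder$type,
    isotropic = diag(builder$sigma2, n3),
    spiked = {
      if (length(builder$u) != n3)
        stop("spike vector length ", length(builder$u), " != 3N = ", n3)
      diag(builder$sigma2, n3) + builder$lambda * tcrossprod(builder$u)
    },
    enm = {
      H <- enm_hessian(mean_coords, builder$cutoff, builder$k)
      e <- eigen(H, symmetric = TRUE)
      # drop the six rigid-body zero modes
      keep <- e$values > 1e-8 * max(e$values)
      e$vectors[, keep, drop = FALSE] %*%
        (t(e$vectors[, keep, drop = FALSE]) / e$values[keep])
    },
    stop("unknown covariance builder type: ", builder$type))
}

# Anisotropic network model Hessian: 3x3 super-element for contact (i,j) is
# -k/d^2 * dx dx^T, diagonals accumulate the negatives.
enm_hessian <- function(coords, cutoff, k) {
  n <- nrow(coords); H <- matrix(0, 3 * n, 3 * n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dx <- coords[j, ] - coords[i, ]
    d2 <- sum(dx^2)
    if (d2 > cutoff^2 || d2 == 0) next
    blk <- -(k / d2) * tcrossprod(dx)
    ii <- (3 * i - 2):(3 * i); jj <- (3 * j - 2):(3 * j)
    H[ii, jj] <- H[ii, jj] + blk
    H[jj, ii] <- H[jj, ii] + blk
    H[ii, ii] <- H[ii, ii] - blk
    H[jj, jj] <- H[jj, jj] - blk
  }
  H
}

#' Unit 3N-vector concentrated on one residue
#'
#' Convenience for planting a spiked covariance mode: zeros everywhere
#' except the 3 coordinates of `residue`, set to `direction` normalized.
#'
#' @param n_residues Number of nodes N.
#' @param residue Node index (1-based).
#' @param direction Length-3 direction (default x).
#' @return Unit vector of length 3N.
#' @export
spike_vector <- function(n_residues, residue, direction = c(1, 0, 0)) {
  stopifnot(residue >= 1, residue <= n_residues)
  u <- numeric(3 * n_residues)
  u[(3 * residue - 2):(3 * residue)] <- direction / sqrt(sum(direction^2))
  u
}

# Default mean geometry: a gentle helix of CA-like nodes, 3.8 A spacing
# along the axis, guaranteed non-collinear for superposition.
default_mean_coords <- function(n_residues) {
  t <- seq_len(n_residues)
  cbind(2.3 * cos(t), 2.3 * sin(t), 1.5 * t)
}

#' Specify a Gaussian fluctuation ensemble
#'
#' @param n_residues Number of CA-like nodes.
#' @param builder A covariance builder (see [covariance_builders]).
#' @param n_frames Number of frames to draw.
#' @param seed Integer seed fixing the sample stream exactly.
#' @param mean_coords Optional N x 3 mean geometry (default: gentle helix).
#' @return A `gaussian_ensemble_spec` object.
#' @export
gaussian_ensemble_spec <- function(n_residues, builder, n_frames, seed,
                                   mean_coords = NULL) {
  stopifnot(n_residues >= 1, n_frames >= 1, inherits(builder, "cov_builder"))
  if (is.null(mean_coords)) mean_coords <- default_mean_coords(n_residues)
  mean_coords <- as.matrix(mean_coords)
  if (nrow(mean_coords) != n_residues || ncol(mean_coords) != 3L)
    stop("mean_coords must be n_residues x 3")
  structure(list(n_residues = n_residues, builder = builder,
                 n_frames = n_frames, seed = as.integer(seed),
                 mean_coords = mean_coords),
            class = "gaussian_ensemble_spec")
}

#' Draw a Gaussian fluctuation ensemble with known covariance
#'
#' Frames are `mean_coords` plus independent draws from the multivariate
#' normal with the builder's covariance, sampled through its eigenbasis.
#' This emulates the positional covariance of CA atoms that linear-response
#' perturbation analysis consumes, with the true covariance known exactly.
#'
#' @param spec A [gaussian_ensemble_spec()].
#' @return List with `trajectory` (a `Trajectory` of CA pseudo-atoms, chain
#'   "A", resid 1..N) and `true_covariance` (3N x 3N, Angstrom^2).
#' @export
generate_gaussian_ensemble <- function(spec) {
  stopifnot(inherits(spec, "gaussian_ensemble_spec"))
  C <- build_covariance_matrix(spec$builder, spec$mean_coords)
  e <- eigen(C, symmetric = TRUE)
  lam <- e$values
  if (any(lam < -1e-8 * max(lam, 0)))
    stop("covariance builder produced a non-PSD matrix (min eigenvalue ",
         format(min(lam)), ")")
  lam[lam < 0] <- 0
  n3 <- length(lam); n <- spec$n_residues
  X <- with_seed(spec$seed, {
    Z <- matrix(rnorm(n3 * spec$n_frames), n3, spec$n_frames)
    e$vectors %*% (sqrt(lam) * Z)
  })
  mu <- as.numeric(t(spec$mean_coords))   # 3N vector, xyz per node
  arr <- array(0, dim = c(n, 3, spec$n_frames))
  for (f in seq_len(spec$n_frames)) {
    arr[, , f] <- matrix(mu + X[, f], ncol = 3, byrow = TRUE)
  }
  topo <- new_structure(
    data.frame(atom_name = "CA", element = "C", resid = seq_len(n),
               resname = "ALA", chain = "A", stringsAsFactors = FALSE),
    spec$mean_coords)
  list(trajectory = new_trajectory(topo, arr),
       true_covariance = C)
}

## --- lipid walk with planted binding kinetics -----------------------------

#' Specify a lipid random walk with planted binding sites
#'
#' Single-bead lipids diffuse in an orthorhombic box with reflecting walls
#' around a fixed protein. Entering within `r_bind` of a site center binds
#' the lipid (it becomes immobile) for a dwell drawn from
#' Exponential(mean = `mean_dwell`); after unbinding the lipid is refractory
#' until it first leaves the capture radius, so dwell segments match the
#' planted distribution exactly.
#'
#' @param box Length-3 box edges, Angstrom.
#' @param n_lipids Number of lipid beads.
#' @param diffusion_step Root-mean-square displacement per frame, Angstrom.
#' @param site_centers Matrix (n_sites x 3) of site centers inside the box.
#' @param r_bind Capture radius, Angstrom.
#' @param mean_dwell Mean of the exponential dwell time, ns.
#' @param frame_dt Frame spacing, ns.
#' @param n_frames Number of frames.
#' @param seed Integer seed.
#' @return A `lipid_kinetics_spec` object.
#' @export
lipid_kinetics_spec <- function(box, n_lipids, diffusion_step, site_centers,
                                r_bind, mean_dwell, frame_dt, n_frames, seed) {
  site_centers <- matrix(as.numeric(site_centers), ncol = 3)
  stopifnot(length(box) == 3, all(box > 0), n_lipids >= 1,
            diffusion_step > 0, r_bind > 0, mean_dwell > 0,
            frame_dt > 0, n_frames >= 1)
  inside <- site_centers >= 0 & sweep(site_centers, 2, box, "<=")
  if (!all(inside)) stop("site center(s) outside the box")
  structure(list(box = as.numeric(box), n_lipids = as.integer(n_lipids),
                 diffusion_step = diffusion_step, site_centers = site_centers,
                 r_bind = r_bind, mean_dwell = mean_dwell,
                 frame_dt = frame_dt, n_frames = as.integer(n_frames),
                 seed = as.integer(seed)),
            class = "lipid_kinetics_spec")
}

reflect_into <- function(x, hi) {
  # fold coordinate into [0, hi] by reflection
  period <- 2 * hi
  x <- x %% period
  ifelse(x > hi, period - x, x)
}

#' Generate a lipid random-walk trajectory with planted binding kinetics
#'
#' @param spec A [lipid_kinetics_spec()].
#' @param protein A `Structure` held fixed in the box (its atoms are
#'   prepended to every frame). May have zero atoms.
#' @param start_coords Optional n_lipids x 3 starting positions (default:
#'   uniform in the box, drawn from the seeded stream).
#' @return A `Trajectory` of protein atoms + one bead per lipid (resname
#'   CHOL, chain "L", atom "R1"). Attribute `planted` records the spec and a
#'   data.frame of binding events (lipid, site, start_frame, end_frame,
#'   dwell_drawn in ns) -- the ground truth for residence-time validation.
#' @export
generate_lipid_walk <- function(spec, protein, start_coords = NULL) {
  stopifnot(inherits(spec, "lipid_kinetics_spec"), inherits(protein, "Structure"))
  nl <- spec$n_lipids; nf <- spec$n_frames
  sigma <- spec$diffusion_step / sqrt(3)   # per-component step SD
  nsite <- nrow(spec$site_centers)
  pos_list <- vector("list", nf)
  events <- list()
  with_seed(spec$seed, {
    pos <- if (is.null(start_coords)) {
      matrix(runif(3 * nl), nl, 3) %*% diag(spec$box)
    } else matrix(as.numeric(start_coords), nl, 3)
    state <- integer(nl)        # 0 free, 1 bound, 2 refractory
    remaining <- numeric(nl)    # ns of dwell left when bound
    bound_site <- integer(nl)
    bind_start <- integer(nl)
    dwell_drawn <- numeric(nl)
    for (f in seq_len(nf)) {
      # always draw a full step block so the stream does not depend on state
      step <- matrix(rnorm(3 * nl, sd = sigma), nl, 3)
      move <- state != 1L
      if (any(move)) {
        newpos <- pos[move, , drop = FALSE] + step[move, , drop = FALSE]
        for (k in 1:3) newpos[, k] <- reflect_into(newpos[, k], spec$box[k])
        pos[move, ] <- newpos
      }
      # distance of every lipid to nearest site
      d2site <- matrix(Inf, nl, nsite)
      for (s in seq_len(nsite)) {
        dx <- sweep(pos, 2, spec$site_centers[s, ])
        d2site[, s] <- rowSums(dx * dx)
      }
      nearest <- max.col(-d2site, ties.method = "first")
      dmin <- sqrt(d2site[cbind(seq_len(nl), nearest)])
      inside <- dmin <= spec$r_bind
      # refractory lipids that have exited become free
      state[state == 2L & !inside] <- 0L
      # free lipids entering the capture radius bind (in lipid order, so the
      # rexp draw sequence is deterministic)
      newly <- which(state == 0L & inside)
      for (i in newly) {
        state[i] <- 1L
        remaining[i] <- rexp(1, rate = 1 / spec$mean_dwell)
        dwell_drawn[i] <- remaining[i]
        bound_site[i] <- nearest[i]
        bind_start[i] <- f
      }
      pos_list[[f]] <- pos
      # advance dwell clocks; expiry releases the lipid into refractory state
      bnd <- which(state == 1L)
      if (length(bnd)) {
        remaining[bnd] <- remaining[bnd] - spec$frame_dt
        done <- bnd[remaining[bnd] <= 0]
        for (i in done) {
          events[[length(events) + 1L]] <- data.frame(
            lipid = i, site = bound_site[i], start_frame = bind_start[i],
            end_frame = f, dwell_drawn = dwell_drawn[i])
          state[i] <- 2L
        }
      }
    }
    # close events still open at the end of the run
    for (i in which(state == 1L)) {
      events[[length(events) + 1L]] <- data.frame(
        lipid = i, site = bound_site[i], start_frame = bind_start[i],
        end_frame = nf, dwell_drawn = dwell_drawn[i])
    }
  })
  np <- n_atoms(protein)
  lip_atoms <- data.frame(
    atom_name = "R1", element = "C",
    resid = seq_len(nl), resname = "CHOL", chain = "L",
    stringsAsFactors = FALSE)
  topo <- new_structure(rbind(protein$atoms, lip_atoms),
                        rbind(protein$coords, pos_list[[1]]))
  arr <- array(0, dim = c(np + nl, 3, nf))
  for (f in seq_len(nf)) {
    if (np > 0) arr[1:np, , f] <- protein$coords
    arr[(np + 1):(np + nl), , f] <- pos_list[[f]]
  }
  traj <- new_trajectory(topo, arr, times = (seq_len(nf) - 1) * spec$frame_dt,
                         box = spec$box)
  planted <- if (length(events)) do.call(rbind, events) else
    data.frame(lipid = integer(0), site = integer(0), start_frame = integer(0),
               end_frame = integer(0), dwell_drawn = numeric(0))
  planted <- planted[order(planted$start_frame, planted$lipid), , drop = FALSE]
  rownames(planted) <- NULL
  attr(traj, "planted") <- list(spec = spec, events = planted)
  traj
}

## --- hydrogen-bond geometry fixture ---------------------------------------

#' Four-atom hydrogen-bond geometry fixture
#'
#' Builds a serine-like O-H donor (OG/HG1, CHARMM naming) and a
#' cholesterol-like hydroxyl acceptor (O3 plus its carbon C3, resname CHL1)
#' with the donor-heavy-atom-to-acceptor distance and D-H-A angle exactly as
#' requested. Used to probe detector cutoffs constructively.
#'
#' @param distance Donor heavy atom (OG) to acceptor (O3) distance, Angstrom.
#' @param angle D-H-A angle at the hydrogen, degrees (0-180).
#' @param oh_bond O-H bond length, Angstrom (default 0.96).
#' @return A `Structure` of 4 atoms: SER OG, SER HG1, CHL1 O3, CHL1 C3.
#' @export
#' @examples
#' s <- hbond_fixture(2.9, 165)
#' sqrt(sum((s$coords[1, ] - s$coords[3, ])^2))  # 2.9
hbond_fixture <- function(distance, angle, oh_bond = 0.96) {
  stopifnot(distance > 0, angle >= 0, angle <= 180)
  r <- oh_bond
  phi <- (180 - angle) * pi / 180      # direction of H->A relative to +x
  # H at (r,0,0); A = H + s*(cos phi, sin phi, 0) with |A - D| = distance
  cs <- cos(phi)
  s_len <- -r * cs + sqrt(r^2 * cs^2 - r^2 + distance^2)
  A <- c(r + s_len * cs, s_len * sin(phi), 0)
  A <- A * (distance / sqrt(sum(A^2)))   # pin |D-A| to the request exactly
  H <- c(r, 0, 0)
  u <- (A - H) / sqrt(sum((A - H)^2))
  C3 <- A + 1.43 * u                   # C-O bond beyond the acceptor
  atoms <- data.frame(
    atom_name = c("OG", "HG1", "O3", "C3"),
    element   = c("O", "H", "O", "C"),
    resid     = c(283L, 283L, 400L, 400L),
    resname   = c("SER", "SER", "CHL1", "CHL1"),
    chain     = c("A", "A", "L", "L"),
    stringsAsFactors = FALSE)
  new_structure(atoms, rbind(c(0, 0, 0), H, A, C3))
}

## --- membrane composition calculator --------------------------------------

#' Mole percents of a leaflet composition
#'
#' Percent = 100 * count / total, rounded half-away-from-zero to one
#' decimal. The rounding rule is stated because published composition
#' tables are typically reported at this precision.
#'
#' @param counts Named non-negative integer vector of lipid counts.
#' @return Named numeric vector of percents (one decimal).
#' @export
#' @examples
#' mole_percents(c(CHOL = 504, POPC = 156, POPE = 252,
#'                 DOPS = 192, PIP2 = 24, SM = 36))
mole_percents <- function(counts) {
  if (length(counts) == 0) stop("empty composition")
  if (any(counts < 0)) stop("negative lipid count")
  total <- sum(counts)
  if (total <= 0) stop("empty composition: total count is zero")
  setNames(round_half_away(100 * counts / total, 1), names(counts))
}

#' Asymmetric neuronal-membrane mimic composition
#'
#' Per-leaflet lipid counts of the six-component asymmetric bilayer used to
#' approximate a neuronal plasma membrane in coarse-grained simulations of
#' glycine receptors: cholesterol-rich in both leaflets, with DOPS and PIP2
#' confined to the inner leaflet.
#'
#' @return data.frame with columns `lipid`, `outer`, `inner` (bead counts).
#' @export
#' @examples
#' comp <- neuronal_membrane_composition()
#' mole_percents(setNames(comp$inner, comp$lipid))
neuronal_membrane_composition <- function() {
  data.frame(
    lipid = c("CHOL", "POPC", "POPE", "DOPS", "PIP2", "SM"),
    outer = c(528L, 288L, 132L, 0L, 0L, 228L),
    inner = c(504L, 156L, 252L, 192L, 24L, 36L),
    stringsAsFactors = FALSE)
}
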