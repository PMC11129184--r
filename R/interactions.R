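# Atomistic interaction analyses: hydrogen-bond and hydrophobic contact
# detection, per-residue interaction fingerprints, atom-pair distance
# series, RMSD series, and a simple pore-radius profile.
#
# Cutoff conventions are uniform across detectors: distances compare with
# <= d_max (inclusive), angles with >= angle_min (inclusive).

# Bondi-style van der Waals radii (Angstrom) for the elements that occur in
# protein/lipid systems; unknown elements fall back to carbon.
VDW_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
               F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, NA. = 2.27, K = 2.75)

#' Van der Waals radius of an element
#' @param element Element symbol(s), e.g. `"C"`.
#' @return Radius in Angstrom (carbon's 1.7 for unknown elements).
#' @export
vdw_radius <- function(element) {
  e <- toupper(element)
  e[e == "NA"] <- "NA."
  r <- VDW_RADII[e]
  r[is.na(r)] <- VDW_RADII[["C"]]
  unname(r)
}

# Hydrogens attached to a donor heavy atom: same residue, element H, within
# a covalent-bond distance (1.25 A). Structure-based, so it is robust to
# naming-scheme variation.
attached_hydrogens <- function(x, donor_idx) {
  a <- x$atoms
  h <- setdiff(which(a$element == "H" &
                       a$chain == a$chain[donor_idx] &
                       a$resid == a$resid[donor_idx]), donor_idx)
  if (!length(h)) return(integer(0))
  d <- sqrt(rowSums((x$coords[h, , drop = FALSE] -
                       matrix(x$coords[donor_idx, ], length(h), 3,
                              byrow = TRUE))^2))
  h[d <= 1.25]
}

#' Hydrogen-bond contacts in one frame
#'
#' Reports (donor, acceptor) atom pairs with donor-heavy-atom-to-acceptor
#' distance <= `d_max` and D-H-A angle >= `angle_min` for at least one
#' hydrogen attached to the donor. Donors without a resolvable hydrogen are
#' skipped; their count is returned as attribute `n_skipped_donors` (with a
#' warning).
#'
#' @param frame A `Structure` (use [get_frame()] on a trajectory). If the
#'   frame has a `box` attribute, distances use the minimum image.
#' @param donors Selection for donor heavy atoms (N/O with attached H).
#' @param acceptors Selection for acceptor atoms.
#' @param d_max Heavy-atom distance cutoff, Angstrom (default 3.5).
#' @param angle_min D-H-A angle cutoff, degrees (default 130).
#' @return data.frame of contacts: donor/acceptor atom indices, chains,
#'   resids, names, distance, angle.
#' @export
hbond_contacts <- function(frame, donors, acceptors, d_max = 3.5,
                           angle_min = 130) {
  stopifnot(inherits(frame, "Structure"))
  box <- attr(frame, "box")
  a <- frame$atoms
  # electronegative heavy atoms only: donors N/O, acceptors N/O/F
  di <- intersect(select_atoms(frame, donors), which(a$element %in% c("N", "O")))
  ai <- intersect(select_atoms(frame, acceptors),
                  which(a$element %in% c("N", "O", "F")))
  rows <- list(); skipped <- 0L
  for (d in di) {
    hs <- attached_hydrogens(frame, d)
    if (!length(hs)) { skipped <- skipped + 1L; next }
    for (acc in ai) {
      if (acc == d) next
      v_da <- min_image(frame$coords[acc, ] - frame$coords[d, ], box)
      dist <- sqrt(sum(v_da^2))
      if (dist > d_max) next
      for (h in hs) {
        v_hd <- min_image(frame$coords[d, ] - frame$coords[h, ], box)
        v_ha <- min_image(frame$coords[acc, ] - frame$coords[h, ], box)
        cosang <- sum(v_hd * v_ha) /
          sqrt(sum(v_hd^2) * sum(v_ha^2))
        ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
        if (ang >= angle_min) {
          rows[[length(rows) + 1L]] <- data.frame(
            donor = d, acceptor = acc,
            donor_chain = a$chain[d], donor_resid = a$resid[d],
            donor_name = a$atom_name[d],
            acceptor_chain = a$chain[acc], acceptor_resid = a$resid[acc],
            acceptor_name = a$atom_name[acc],
            distance = dist, angle = ang, stringsAsFactors = FALSE)
          break
        }
      }
    }
  }
  if (skipped > 0L)
    warning(skipped, " donor atom(s) had no resolvable attached hydrogen")
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(donor = integer(0), acceptor = integer(0),
               donor_chain = character(0), donor_resid = integer(0),
               donor_name = character(0), acceptor_chain = character(0),
               acceptor_resid = integer(0), acceptor_name = character(0),
               distance = numeric(0), angle = numeric(0),
               stringsAsFactors = FALSE)
  attr(out, "n_skipped_donors") <- skipped
  out
}

#' Hydrophobic contacts in one frame
#'
#' Residue-level pairs between the two selections with any carbon/sulfur
#' atom pair within `d_max` (minimum image when the frame carries a box).
#'
#' @param frame A `Structure`.
#' @param sel_a,sel_b Selections (restricted internally to C and S atoms).
#' @param d_max Distance cutoff, Angstrom (default 4.5).
#' @return data.frame of residue pairs (chain_a, resid_a, chain_b, resid_b,
#'   min_distance).
#' @export
hydrophobic_contacts <- function(frame, sel_a, sel_b, d_max = 4.5) {
  stopifnot(inherits(frame, "Structure"))
  box <- attr(frame, "box")
  a <- frame$atoms
  ia <- intersect(select_atoms(frame, sel_a), which(a$element %in% c("C", "S")))
  ib <- intersect(select_atoms(frame, sel_b), which(a$element %in% c("C", "S")))
  if (!length(ia) || !length(ib))
    return(data.frame(chain_a = character(0), resid_a = integer(0),
                      chain_b = character(0), resid_b = integer(0),
                      min_distance = numeric(0), stringsAsFactors = FALSE))
  D <- pair_dist_matrix(frame$coords[ia, , drop = FALSE],
                        frame$coords[ib, , drop = FALSE], box)
  key_a <- paste(a$chain[ia], a$resid[ia], sep = "\r")
  key_b <- paste(a$chain[ib], a$resid[ib], sep = "\r")
  rows <- list()
  for (ka in unique(key_a)) for (kb in unique(key_b)) {
    if (ka == kb) next
    sub <- D[key_a == ka, key_b == kb, drop = FALSE]
    m <- min(sub)
    if (m <= d_max) {
      pa <- strsplit(ka, "\r")[[1]]; pb <- strsplit(kb, "\r")[[1]]
      rows[[length(rows) + 1L]] <- data.frame(
        chain_a = pa[1], resid_a = as.integer(pa[2]),
        chain_b = pb[1], resid_b = as.integer(pb[2]),
        min_distance = m, stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(chain_a = character(0), resid_a = integer(0),
               chain_b = character(0), resid_b = integer(0),
               min_distance = numeric(0), stringsAsFactors = FALSE)
}

#' Ligand-protein interaction fingerprint over a trajectory
#'
#' Per-frame boolean contacts between the ligand and each protein residue,
#' classified as `hbond_donor` (protein donates H to the ligand),
#' `hbond_acceptor` (protein accepts from the ligand) and `hydrophobic`,
#' aggregated to per-residue frame fractions. Pass a list of trajectories
#' for replicas: per-replica tables are returned plus a frame-weighted
#' pooled table. Aromatic stacking and cation-pi classes are out of scope
#' (irrelevant for sterols).
#'
#' @param traj A `Trajectory` or list of trajectories (replicas).
#' @param ligand_sel Selection for the ligand.
#' @param protein_sel Selection for the protein.
#' @param hbond_dmax,hbond_angle_min H-bond cutoffs (3.5 Angstrom, 130 deg).
#' @param hydrophobic_dmax Hydrophobic cutoff (4.5 Angstrom).
#' @return A `FingerprintTable`: data.frame (chain, resid, resname,
#'   hbond_donor, hbond_acceptor, hydrophobic) of frame fractions;
#'   attribute `replicas` holds the per-replica tables when pooled.
#' @export
fingerprint <- function(traj, ligand_sel, protein_sel,
                        hbond_dmax = 3.5, hbond_angle_min = 130,
                        hydrophobic_dmax = 4.5) {
  if (inherits(traj, "Trajectory")) {
    tab <- fingerprint_single(traj, ligand_sel, protein_sel,
                              hbond_dmax, hbond_angle_min, hydrophobic_dmax)
    return(tab)
  }
  stopifnot(is.list(traj), length(traj) >= 1)
  reps <- lapply(traj, fingerprint_single, ligand_sel, protein_sel,
                 hbond_dmax, hbond_angle_min, hydrophobic_dmax)
  nfs <- vapply(traj, n_frames, numeric(1))
  key <- function(t) paste(t$chain, t$resid, sep = "\r")
  all_keys <- unique(unlist(lapply(reps, key)))
  pooled <- NULL
  for (i in seq_along(reps)) {
    t <- reps[[i]]
    m <- match(all_keys, key(t))
    vals <- t[m, c("hbond_donor", "hbond_acceptor", "hydrophobic")]
    vals[is.na(vals)] <- 0
    if (is.null(pooled)) {
      pooled <- t[m, c("chain", "resid", "resname")]
      miss <- is.na(pooled$resid)
      acc <- as.matrix(vals) * nfs[i]
    } else {
      fill <- is.na(pooled$resid) & !is.na(m)
      pooled[fill, ] <- t[m[fill], c("chain", "resid", "resname")]
      acc <- acc + as.matrix(vals) * nfs[i]
    }
  }
  out <- cbind(pooled, as.data.frame(acc / sum(nfs)))
  out <- out[order(out$chain, out$resid), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "replicas") <- reps
  attr(out, "n_frames") <- sum(nfs)
  class(out) <- c("FingerprintTable", "data.frame")
  out
}

fingerprint_single <- function(traj, ligand_sel, protein_sel,
                               hbond_dmax, hbond_angle_min, hydrophobic_dmax) {
  stopifnot(inherits(traj, "Trajectory"))
  li <- select_atoms(traj$topology, ligand_sel)
  if (!length(li)) stop("empty ligand selection: '", ligand_sel, "'")
  pi_ <- select_atoms(traj$topology, protein_sel)
  if (!length(pi_)) stop("empty protein selection: '", protein_sel, "'")
  residues <- residue_nodes(traj$topology, pi_)
  key_r <- paste(residues$chain, residues$resid, sep = "\r")
  nf <- n_frames(traj)
  counts <- matrix(0L, nrow(residues), 3,
                   dimnames = list(NULL, c("hbond_donor", "hbond_acceptor",
                                           "hydrophobic")))
  for (f in seq_len(nf)) {
    fr <- get_frame(traj, f)
    # protein donates to ligand acceptors
    hb1 <- suppressWarnings(
      hbond_contacts(fr, protein_sel, ligand_sel, hbond_dmax, hbond_angle_min))
    if (nrow(hb1)) {
      hit <- unique(match(paste(hb1$donor_chain, hb1$donor_resid, sep = "\r"),
                          key_r))
      counts[hit[!is.na(hit)], "hbond_donor"] <-
        counts[hit[!is.na(hit)], "hbond_donor"] + 1L
    }
    # ligand donates to protein acceptors
    hb2 <- suppressWarnings(
      hbond_contacts(fr, ligand_sel, protein_sel, hbond_dmax, hbond_angle_min))
    if (nrow(hb2)) {
      hit <- unique(match(paste(hb2$acceptor_chain, hb2$acceptor_resid,
                                sep = "\r"), key_r))
      counts[hit[!is.na(hit)], "hbond_acceptor"] <-
        counts[hit[!is.na(hit)], "hbond_acceptor"] + 1L
    }
    hp <- hydrophobic_contacts(fr, protein_sel, ligand_sel, hydrophobic_dmax)
    if (nrow(hp)) {
      hit <- unique(match(paste(hp$chain_a, hp$resid_a, sep = "\r"), key_r))
      counts[hit[!is.na(hit)], "hydrophobic"] <-
        counts[hit[!is.na(hit)], "hydrophobic"] + 1L
    }
  }
  out <- cbind(residues, as.data.frame(counts / nf))
  rownames(out) <- NULL
  attr(out, "n_frames") <- nf
  class(out) <- c("FingerprintTable", "data.frame")
  out
}

#' Atom-pair distance series
#'
#' Per-frame minimum-image distance between two named atoms. If either
#' selection resolves to multiple atoms (e.g. one ligand copy per subunit),
#' series are paired by order (m vs m) or broadcast (m vs 1), and pooled
#' mean/SD over all copies and frames are reported alongside per-copy
#' summaries. SD is the population form (denominator n).
#'
#' @param traj A `Trajectory`.
#' @param atom_a,atom_b Selection strings each resolving to >= 1 atom.
#' @return List with `series` (frames x copies matrix, ns times as
#'   rownames omitted -- see `times`), `times`, `per_copy` (mean, sd),
#'   `mean`, `sd` (pooled).
#' @export
pair_distance_series <- function(traj, atom_a, atom_b) {
  stopifnot(inherits(traj, "Trajectory"))
  ia <- select_atoms(traj$topology, atom_a)
  ib <- select_atoms(traj$topology, atom_b)
  if (!length(ia)) stop("atom lookup failed for selection '", atom_a, "'")
  if (!length(ib)) stop("atom lookup failed for selection '", atom_b, "'")
  if (length(ia) != length(ib)) {
    if (length(ia) == 1L) ia <- rep(ia, length(ib))
    else if (length(ib) == 1L) ib <- rep(ib, length(ia))
    else stop("selections resolve to ", length(ia), " and ", length(ib),
              " atoms; need equal counts or one singleton")
  }
  nc <- length(ia); nf <- n_frames(traj)
  ser <- matrix(0, nf, nc)
  for (f in seq_len(nf)) {
    box <- if (!is.null(traj$box)) traj$box[f, ] else NULL
    dx <- traj$coords[ia, , f, drop = FALSE][, , 1] -
      traj$coords[ib, , f, drop = FALSE][, , 1]
    if (is.null(dim(dx))) dx <- matrix(dx, ncol = 3)
    dx <- min_image(dx, box)
    ser[f, ] <- sqrt(rowSums(dx^2))
  }
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  list(series = ser, times = traj$times,
       per_copy = data.frame(copy = seq_len(nc),
                             mean = colMeans(ser),
                             sd = apply(ser, 2, pop_sd)),
       mean = mean(ser), sd = pop_sd(as.numeric(ser)))
}

#' RMSD time series against a reference structure
#'
#' Per-frame Kabsch-superposed RMSD of the selection to the corresponding
#' atoms of `reference`.
#'
#' @param traj A `Trajectory`.
#' @param selection Selection applied to both trajectory topology and
#'   reference.
#' @param reference A `Structure` (default: frame 1).
#' @return Numeric vector of per-frame RMSD in Angstrom.
#' @export
rmsd_series <- function(traj, selection = "name CA", reference = NULL) {
  stopifnot(inherits(traj, "Trajectory"))
  if (is.null(reference)) reference <- get_frame(traj, 1)
  it <- select_atoms(traj$topology, selection)
  ir <- select_atoms(reference, selection)
  if (length(it) != length(ir) || !length(it))
    stop("correspondence error: selection resolves to ", length(it),
         " trajectory atoms vs ", length(ir), " reference atoms")
  ref <- reference$coords[ir, , drop = FALSE]
  vapply(seq_len(n_frames(traj)), function(f)
    superpose_kabsch(traj$coords[it, , f], ref)$rmsd, numeric(1))
}

#' Simple pore-radius profile along a channel axis
#'
#' Partitions atoms into slabs along the pore axis and reports, per slab,
#' min over slab atoms of (distance to the axis - vdW radius of the
#' element), restricted to atoms within a search cylinder. The axis is the
#' principal axis of the `axis_sel` atoms (default all CA) through the
#' centroid of `lining_sel` (default: same selection). Slabs with no atoms
#' are flagged undefined (NA radius), not zero-filled. This is a
#' straight-axis radius profile; no curved-pathway search is attempted.
#'
#' @param structure A `Structure`.
#' @param lining_sel Selection for pore-lining atoms evaluated per slab
#'   (default `"all"` = every atom).
#' @param axis_sel Selection defining the axis direction (default
#'   `"name CA"`).
#' @param slab Slab thickness, Angstrom (default 1).
#' @param search_radius Cylinder radius around the axis, Angstrom
#'   (default 15).
#' @return A `PoreProfile` data.frame: z (slab center along the axis,
#'   Angstrom), radius (Angstrom, NA where undefined), n_atoms.
#' @export
pore_profile <- function(structure, lining_sel = "all", axis_sel = "name CA",
                         slab = 1, search_radius = 15) {
  stopifnot(inherits(structure, "Structure"), slab > 0)
  idx <- if (identical(lining_sel, "all")) seq_len(n_atoms(structure))
         else select_atoms(structure, lining_sel)
  if (!length(idx)) stop("empty pore-lining selection")
  ax_idx <- tryCatch(select_atoms(structure, axis_sel), error = function(e) idx)
  if (length(ax_idx) < 3L) ax_idx <- idx
  axc <- structure$coords[ax_idx, , drop = FALSE]
  if (nrow(axc) >= 3L) {
    pc <- eigen(stats::cov(axc), symmetric = TRUE)
    axis <- pc$vectors[, 1]
  } else axis <- c(0, 0, 1)
  axis <- axis / sqrt(sum(axis^2))
  center <- colMeans(structure$coords[idx, , drop = FALSE])
  rel <- sweep(structure$coords[idx, , drop = FALSE], 2, center)
  z <- as.numeric(rel %*% axis)
  radial <- sqrt(pmax(0, rowSums(rel^2) - z^2))
  keep <- radial <= search_radius
  z <- z[keep]; radial <- radial[keep]
  elements <- structure$atoms$element[idx][keep]
  if (!length(z)) stop("no atoms inside the search cylinder")
  zmin <- floor(min(z) / slab) * slab
  zmax <- ceiling(max(z) / slab) * slab
  edges <- seq(zmin, zmax, by = slab)
  nb <- length(edges) - 1L
  out <- data.frame(z = edges[-length(edges)] + slab / 2,
                    radius = NA_real_, n_atoms = 0L)
  bin <- pmin(nb, pmax(1L, findInterval(z, edges, rightmost.closed = TRUE)))
  for (b in unique(bin)) {
    sel <- bin == b
    out$n_atoms[b] <- sum(sel)
    out$radius[b] <- min(radial[sel] - vdw_radius(elements[sel]))
  }
  class(out) <- c("PoreProfile", "data.frame")
  attr(out, "axis") <- axis
  attr(out, "center") <- center
  out
}
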