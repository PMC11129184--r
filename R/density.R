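# Lipid occupancy density grids.
#
# A voxel's occupancy is the fraction of frames in which at least one
# selected particle falls in it (binning is half-open,
# [origin + k*s, origin + (k+1)*s)); reporting uses an occupancy-fraction
# threshold (default 0.5: present in at least half of the frames) and an
# optional protein-proximity mask. Grids are written as OpenDX scalar
# fields for visualization alongside VMD Volmap outputs.

#' Construct an OccupancyGrid
#' @param origin Length-3 grid origin, Angstrom.
#' @param spacing Voxel edge, Angstrom.
#' @param values 3D array of per-voxel occupancy fractions in [0, 1].
#' @param lipid_type Label for the mapped species.
#' @param n_frames Frames averaged over.
#' @return An `OccupancyGrid`.
#' @export
new_occupancy_grid <- function(origin, spacing, values, lipid_type = "",
                               n_frames = NA_integer_) {
  values <- as.array(values)
  if (length(dim(values)) != 3L) stop("values must be a 3D array")
  if (any(values < -1e-12 | values > 1 + 1e-12))
    stop("occupancy values must lie in [0, 1]")
  structure(list(origin = as.numeric(origin), spacing = as.numeric(spacing),
                 dims = dim(values), values = values,
                 lipid_type = lipid_type, n_frames = n_frames),
            class = "OccupancyGrid")
}

#' @export
print.OccupancyGrid <- function(x, ...) {
  cat("OccupancyGrid:", paste(x$dims, collapse = " x "), "voxels @",
      x$spacing, "Angstrom;", sum(x$values > 0), "occupied;",
      if (nzchar(x$lipid_type)) paste0("species ", x$lipid_type, ";") else "",
      x$n_frames, "frames\n")
  invisible(x)
}

#' Time-averaged occupancy grid for one particle selection
#'
#' Voxel value = (number of frames in which >= 1 selected particle falls in
#' the voxel) / n_frames. Particles are wrapped into the primary box image
#' before binning; the grid origin is the box minimum corner (0,0,0) and the
#' grid covers the whole box. Requires a constant orthorhombic box.
#'
#' @param traj A `Trajectory` with a box.
#' @param selection Selection string for the mapped species (e.g.
#'   `"resname CHOL"`).
#' @param spacing Voxel edge in Angstrom (default 1.0).
#' @param lipid_type Label stored with the grid (default: the selection).
#' @return An `OccupancyGrid`.
#' @export
compute_occupancy <- function(traj, selection, spacing = 1.0,
                              lipid_type = selection) {
  stopifnot(inherits(traj, "Trajectory"), spacing > 0)
  if (is.null(traj$box)) stop("occupancy requires a trajectory with box vectors")
  box <- traj$box[1, ]
  if (any(abs(sweep(traj$box, 2, box)) > 1e-6))
    stop("varying box across frames is unsupported for occupancy grids")
  idx <- select_atoms(traj$topology, selection)
  if (!length(idx)) stop("empty selection: '", selection, "'")
  dims <- as.integer(ceiling(box / spacing - 1e-9))
  dims[dims < 1L] <- 1L
  counts <- array(0L, dim = dims)
  nf <- n_frames(traj)
  for (f in seq_len(nf)) {
    xyz <- traj$coords[idx, , f, drop = FALSE][, , 1, drop = TRUE]
    if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
    vox <- matrix(0L, nrow(xyz), 3)
    for (k in 1:3) {
      xk <- xyz[, k] %% box[k]                 # wrap into [0, box)
      vox[, k] <- pmin(dims[k] - 1L, as.integer(floor(xk / spacing)))
    }
    lin <- unique(1L + vox[, 1] + dims[1] * (vox[, 2] + dims[2] * vox[, 3]))
    counts[lin] <- counts[lin] + 1L
  }
  new_occupancy_grid(c(0, 0, 0), spacing, counts / nf, lipid_type, nf)
}

#' Protein-proximity voxel mask
#'
#' TRUE for voxels whose center lies within `cutoff` of any atom of
#' `protein` (no periodic wrap: the mask is for the reporting filter around
#' a protein fixed in the box interior).
#'
#' @param grid An `OccupancyGrid`.
#' @param protein A `Structure` (typically the mean structure).
#' @param cutoff Distance cutoff in Angstrom (default 6).
#' @return Logical 3D array shaped like the grid.
#' @export
proximity_mask <- function(grid, protein, cutoff = 6) {
  stopifnot(inherits(grid, "OccupancyGrid"), inherits(protein, "Structure"))
  d <- grid$dims
  centers_x <- grid$origin[1] + (seq_len(d[1]) - 0.5) * grid$spacing
  centers_y <- grid$origin[2] + (seq_len(d[2]) - 0.5) * grid$spacing
  centers_z <- grid$origin[3] + (seq_len(d[3]) - 0.5) * grid$spacing
  mask <- array(FALSE, dim = d)
  p <- protein$coords
  if (nrow(p) == 0L) return(mask)
  c2 <- cutoff^2
  # per-voxel min distance; grids here are small (analysis boxes of toys)
  for (iz in seq_len(d[3])) {
    dz2 <- (centers_z[iz] - p[, 3])^2
    near <- dz2 <= c2
    if (!any(near)) next
    pz <- p[near, , drop = FALSE]; dz2 <- dz2[near]
    for (iy in seq_len(d[2])) {
      dyz2 <- dz2 + (centers_y[iy] - pz[, 2])^2
      near2 <- dyz2 <= c2
      if (!any(near2)) next
      px <- pz[near2, 1]; dyz2b <- dyz2[near2]
      for (ix in seq_len(d[1])) {
        if (any(dyz2b + (centers_x[ix] - px)^2 <= c2)) mask[ix, iy, iz] <- TRUE
      }
    }
  }
  mask
}

#' Apply the occupancy reporting filter to a grid
#'
#' Zeroes voxels below `min_occupancy` (the threshold itself is kept:
#' inclusive comparison). With a mask (logical array or an
#' `OccupancyGrid`-shaped object from [proximity_mask()]), voxels outside
#' the mask are also zeroed -- this realizes the "in contact with the
#' protein in at least the given fraction of frames" reading of the filter.
#'
#' @param grid An `OccupancyGrid`.
#' @param min_occupancy Fraction threshold in [0, 1] (default 0.5).
#' @param mask Optional logical 3D array shaped like the grid.
#' @return A filtered `OccupancyGrid`.
#' @export
threshold_grid <- function(grid, min_occupancy = 0.5, mask = NULL) {
  stopifnot(inherits(grid, "OccupancyGrid"))
  if (min_occupancy < 0 || min_occupancy > 1)
    stop("min_occupancy must be in [0, 1]")
  v <- grid$values
  v[v < min_occupancy] <- 0
  if (!is.null(mask)) {
    mask <- as.array(mask)
    if (!identical(dim(mask), grid$dims))
      stop("mask shape ", paste(dim(mask), collapse = "x"),
           " does not match grid ", paste(grid$dims, collapse = "x"))
    v[!mask] <- 0
  }
  out <- grid
  out$values <- v
  out
}

#' Write an OccupancyGrid as an OpenDX scalar field
#'
#' Standard `object 1/2/3` OpenDX layout (as produced by VMD Volmap and
#' read by gridDataFormats/PyMOL/VMD), data in C order (z fastest), three
#' values per line.
#'
#' @param grid An `OccupancyGrid`.
#' @param path Output path (conventionally `.dx`).
#' @return Invisibly, `path`.
#' @export
write_dx <- function(grid, path) {
  stopifnot(inherits(grid, "OccupancyGrid"))
  d <- grid$dims; s <- grid$spacing; o <- grid$origin
  n <- prod(d)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# OpenDX density file written by memallo (species: %s, %s frames)",
            grid$lipid_type, grid$n_frames),
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.6f %.6f %.6f", o[1], o[2], o[3]),
    sprintf("delta %.6f 0.000000 0.000000", s),
    sprintf("delta 0.000000 %.6f 0.000000", s),
    sprintf("delta 0.000000 0.000000 %.6f", s),
    sprintf("object 2 class gridconnections counts %d %d %d", d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows", n)
  ), con)
  # C order: x slowest, z fastest
  vals <- as.numeric(aperm(grid$values, c(3, 2, 1)))
  nfull <- (length(vals) %/% 3L) * 3L
  if (nfull > 0) {
    m <- matrix(vals[seq_len(nfull)], ncol = 3, byrow = TRUE)
    writeLines(sprintf("%.8g %.8g %.8g", m[, 1], m[, 2], m[, 3]), con)
  }
  if (nfull < length(vals))
    writeLines(paste(sprintf("%.8g", vals[(nfull + 1):length(vals)]),
                     collapse = " "), con)
  writeLines(c('attribute "dep" string "positions"',
               'object "density" class field',
               'component "positions" value 1',
               'component "connections" value 2',
               'component "data" value 3'), con)
  invisible(path)
}

#' Read an OpenDX scalar field back into an OccupancyGrid
#'
#' Supports regular grids with axis-aligned deltas (the layout [write_dx()]
#' produces and VMD Volmap emits).
#'
#' @param path Path to a `.dx` file.
#' @return An `OccupancyGrid` (lipid_type/n_frames metadata not recovered).
#' @export
read_dx <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines)]
  g1 <- grep("gridpositions counts", lines, value = TRUE)[1]
  if (is.na(g1)) stop("not an OpenDX grid: ", path)
  d <- as.integer(tail(strsplit(trimws(g1), "\\s+")[[1]], 3))
  o <- as.numeric(tail(strsplit(trimws(
    grep("^origin", lines, value = TRUE)[1]), "\\s+")[[1]], 3))
  deltas <- grep("^delta", lines, value = TRUE)[1:3]
  dm <- t(vapply(deltas, function(l)
    as.numeric(tail(strsplit(trimws(l), "\\s+")[[1]], 3)), numeric(3)))
  offdiag <- dm; diag(offdiag) <- 0
  if (any(abs(offdiag) > 1e-9)) stop("non-axis-aligned DX deltas unsupported")
  if (max(abs(diag(dm) - dm[1, 1])) > 1e-9)
    stop("anisotropic DX spacing unsupported")
  start <- grep("data follows", lines)[1]
  endl <- grep("^attribute|^object \"", lines)
  endl <- endl[endl > start]
  stop_at <- if (length(endl)) min(endl) - 1L else length(lines)
  vals <- as.numeric(unlist(strsplit(trimws(lines[(start + 1):stop_at]), "\\s+")))
  if (length(vals) != prod(d))
    stop("DX data length ", length(vals), " != ", prod(d))
  arr <- aperm(array(vals, dim = rev(d)), c(3, 2, 1))
  new_occupancy_grid(o, dm[1, 1], arr)
}
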