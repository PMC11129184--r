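# Trajectory data model plus a binary DCD codec.
#
# Internal units: Angstrom and ns. DCD stores coordinates in Angstrom
# already; the header DELTA field is written/read as the frame spacing in
# picoseconds (the common GROMACS/CHARMM tooling convention) and converted
# to ns at this boundary. Only orthorhombic unit cells are supported; a
# triclinic cell record raises an explicit error.

#' Construct a Trajectory
#'
#' @param topology A `Structure` describing every particle.
#' @param coords Either a list of N x 3 matrices (one per frame) or an
#'   N x 3 x n_frames array, coordinates in Angstrom.
#' @param times Frame times in ns, strictly increasing. Defaults to
#'   `0:(n_frames-1)`.
#' @param box Per-frame orthorhombic box edge lengths in Angstrom: an
#'   n_frames x 3 matrix, a single length-3 vector (recycled), or NULL.
#' @return An object of class `Trajectory`.
#' @export
new_trajectory <- function(topology, coords, times = NULL, box = NULL) {
  stopifnot(inherits(topology, "Structure"))
  if (is.list(coords)) {
    nf <- length(coords)
    if (nf == 0L) stop("trajectory needs at least one frame")
    arr <- array(0, dim = c(nrow(coords[[1]]), 3, nf))
    for (i in seq_len(nf)) arr[, , i] <- coords[[i]]
    coords <- arr
  }
  if (length(dim(coords)) != 3L || dim(coords)[2] != 3L)
    stop("coords must be an N x 3 x n_frames array or list of N x 3 matrices")
  n <- dim(coords)[1]; nf <- dim(coords)[3]
  if (n != n_atoms(topology))
    stop("frame atom count (", n, ") does not match topology (",
         n_atoms(topology), ")")
  if (is.null(times)) times <- as.numeric(seq_len(nf) - 1L)
  if (length(times) != nf) stop("times length must equal frame count")
  if (nf > 1L && any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (!is.null(box)) {
    if (is.null(dim(box))) box <- matrix(box, nrow = nf, ncol = 3, byrow = TRUE)
    box <- as.matrix(box)
    if (nrow(box) != nf || ncol(box) != 3L)
      stop("box must be an n_frames x 3 matrix of edge lengths")
    if (any(box <= 0)) stop("box edge lengths must be positive")
  }
  structure(list(topology = topology, coords = coords,
                 times = as.numeric(times), box = box),
            class = "Trajectory")
}

#' @export
print.Trajectory <- function(x, ...) {
  cat("Trajectory:", dim(x$coords)[3], "frames x", dim(x$coords)[1],
      "atoms,", sprintf("%.4g-%.4g ns", x$times[1], tail(x$times, 1)),
      if (is.null(x$box)) "(no box)" else "(orthorhombic box)", "\n")
  invisible(x)
}

#' Number of frames in a Trajectory
#' @param x A `Trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(x) dim(x$coords)[3]

#' Extract one frame as a Structure
#' @param x A `Trajectory`.
#' @param i Frame index (1-based).
#' @return A `Structure`; the frame box (if any) is attached as attribute `box`.
#' @export
get_frame <- function(x, i) {
  stopifnot(inherits(x, "Trajectory"), i >= 1, i <= n_frames(x))
  out <- new_structure(x$topology$atoms, x$coords[, , i])
  if (!is.null(x$box)) attr(out, "box") <- x$box[i, ]
  out
}

# Mean coordinates over frames (no alignment), N x 3.
mean_coords <- function(x, frames = seq_len(n_frames(x))) {
  apply(x$coords[, , frames, drop = FALSE], c(1, 2), mean)
}

## --- DCD codec ------------------------------------------------------------

write_record <- function(con, raw_writer, nbytes) {
  writeBin(as.integer(nbytes), con, size = 4)
  raw_writer()
  writeBin(as.integer(nbytes), con, size = 4)
}

#' Write a Trajectory to a DCD file
#'
#' CHARMM-style DCD with a unit-cell record per frame (orthorhombic; the
#' three 90-degree angle slots hold cosines, i.e. zero). Coordinates are
#' single precision, so round-trip accuracy is ~1e-6 relative.
#'
#' @param traj A `Trajectory`. Frame times must be uniformly spaced (the DCD
#'   header carries a single spacing).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_dcd <- function(traj, path) {
  stopifnot(inherits(traj, "Trajectory"))
  nf <- n_frames(traj); n <- dim(traj$coords)[1]
  dt_ns <- if (nf > 1) traj$times[2] - traj$times[1] else 1
  has_cell <- !is.null(traj$box)
  con <- file(path, "wb")
  on.exit(close(con))
  icntrl <- integer(20)
  icntrl[1] <- nf; icntrl[2] <- 1L; icntrl[3] <- 1L; icntrl[4] <- nf
  icntrl[11] <- if (has_cell) 1L else 0L
  icntrl[20] <- 24L
  write_record(con, function() {
    writeBin(charToRaw("CORD"), con)
    writeBin(icntrl[1:9], con, size = 4)
    writeBin(as.numeric(dt_ns * 1000), con, size = 4)  # DELTA in ps
    writeBin(icntrl[11:20], con, size = 4)
  }, 84L)
  title <- sprintf("%-80s", "memallo trajectory")
  write_record(con, function() {
    writeBin(1L, con, size = 4)
    writeBin(charToRaw(title), con)
  }, 84L)
  write_record(con, function() writeBin(as.integer(n), con, size = 4), 4L)
  for (f in seq_len(nf)) {
    if (has_cell) {
      b <- traj$box[f, ]
      cell <- c(b[1], 0, b[2], 0, 0, b[3])
      write_record(con, function() writeBin(cell, con, size = 8), 48L)
    }
    for (k in 1:3)
      write_record(con, function() writeBin(as.numeric(traj$coords[, k, f]),
                                            con, size = 4), 4L * n)
  }
  invisible(path)
}

read_record <- function(con, what, size, n, where) {
  len <- readBin(con, "integer", 1, size = 4)
  if (length(len) == 0L) return(NULL)
  dat <- readBin(con, what, n, size = size)
  tail_len <- readBin(con, "integer", 1, size = 4)
  if (length(dat) < n || length(tail_len) == 0L || tail_len != len)
    stop("truncated or corrupt DCD record (", where, ")")
  dat
}

#' Read a DCD trajectory file
#'
#' @param path Path to a DCD file.
#' @param n_atoms_expected Optional atom count to validate against.
#' @return List with `coords` (N x 3 x n_frames array, Angstrom), `box`
#'   (n_frames x 3 or NULL), `dt_ns` (frame spacing).
#' @export
read_dcd <- function(path, n_atoms_expected = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  len <- readBin(con, "integer", 1, size = 4)
  if (!identical(len, 84L)) stop("not a DCD file (bad header length): ", path)
  magic <- rawToChar(readBin(con, "raw", 4))
  if (magic != "CORD") stop("not a DCD file (magic '", magic, "'): ", path)
  icntrl_a <- readBin(con, "integer", 9, size = 4)
  delta <- readBin(con, "numeric", 1, size = 4)
  icntrl_b <- readBin(con, "integer", 10, size = 4)
  readBin(con, "integer", 1, size = 4)  # trailing length
  has_cell <- icntrl_b[1] == 1L
  tlen <- readBin(con, "integer", 1, size = 4)
  readBin(con, "raw", tlen)                      # title block (ignored)
  readBin(con, "integer", 1, size = 4)
  natoms <- read_record(con, "integer", 4, 1, "atom count")
  if (!is.null(n_atoms_expected) && natoms != n_atoms_expected)
    stop("topology error: DCD has ", natoms, " atoms, structure has ",
         n_atoms_expected)
  frames <- list(); boxes <- list(); f <- 0L
  repeat {
    if (has_cell) {
      cell <- tryCatch(read_record(con, "numeric", 8, 6, paste0("frame ", f + 1)),
                       error = function(e) stop(conditionMessage(e),
                                                "; last good frame: ", f))
      if (is.null(cell)) break
      # CHARMM cell record: [a, cos(gamma), b, cos(beta), cos(alpha), c]
      if (any(abs(cell[c(2, 4, 5)]) > 1e-6))
        stop("triclinic boxes are not supported (frame ", f + 1, ")")
      boxes[[f + 1L]] <- cell[c(1, 3, 6)]
    }
    xyz <- tryCatch(list(
      x = read_record(con, "numeric", 4, natoms, paste0("frame ", f + 1)),
      y = read_record(con, "numeric", 4, natoms, paste0("frame ", f + 1)),
      z = read_record(con, "numeric", 4, natoms, paste0("frame ", f + 1))),
      error = function(e) stop(conditionMessage(e),
                               "; last good frame: ", f, call. = FALSE))
    xs <- xyz$x; ys <- xyz$y; zs <- xyz$z
    if (is.null(xs)) break
    if (is.null(ys) || is.null(zs))
      stop("truncated DCD; last good frame: ", f)
    f <- f + 1L
    frames[[f]] <- cbind(xs, ys, zs)
  }
  if (f == 0L) stop("empty DCD: no frames in ", path)
  arr <- array(0, dim = c(natoms, 3, f))
  for (i in seq_len(f)) arr[, , i] <- frames[[i]]
  box <- if (has_cell) do.call(rbind, boxes) else NULL
  list(coords = arr, box = box, dt_ns = delta / 1000)
}

#' Read a structure + trajectory pair
#'
#' The structure file (PDB or GRO) supplies the topology; the trajectory
#' file supplies frames. DCD is the supported binary dialect; XTC input is
#' rejected with an explicit unsupported-format error (no XTC codec is
#' bundled).
#'
#' @param structure_path PDB or GRO file.
#' @param trajectory_path DCD file.
#' @return A `Trajectory`.
#' @export
read_trajectory <- function(structure_path, trajectory_path) {
  ext_s <- tolower(tools::file_ext(structure_path))
  top <- switch(ext_s,
                pdb = read_pdb(structure_path),
                gro = read_gro(structure_path),
                stop("unsupported structure format: .", ext_s))
  ext_t <- tolower(tools::file_ext(trajectory_path))
  if (ext_t == "xtc")
    stop("XTC input is not supported; convert to DCD ",
         "(e.g. `mdconvert` or `gmx trjconv` + catdcd) or load coordinates ",
         "directly with new_trajectory()")
  if (ext_t != "dcd") stop("unsupported trajectory format: .", ext_t)
  raw <- read_dcd(trajectory_path, n_atoms_expected = n_atoms(top))
  nf <- dim(raw$coords)[3]
  new_trajectory(top, raw$coords,
                 times = (seq_len(nf) - 1L) * raw$dt_ns,
                 box = raw$box)
}
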