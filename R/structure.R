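# Structure data model and PDB/GRO readers.
#
# A Structure is the minimal topology needed by the analyses: per-atom
# name/element/residue/chain plus an N x 3 coordinate matrix in Angstrom.
# Atom lookup is always by (chain, residue number, atom name); file order is
# preserved but never assumed sorted.

#' Construct a Structure
#'
#' @param atoms data.frame with columns `atom_name`, `element`, `resid`
#'   (1-based PDB residue number), `resname`, `chain`.
#' @param coords Numeric N x 3 matrix of coordinates in Angstrom.
#' @return An object of class `Structure`.
#' @export
new_structure <- function(atoms, coords) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  need <- c("atom_name", "element", "resid", "resname", "chain")
  miss <- setdiff(need, names(atoms))
  if (length(miss))
    stop("atoms table missing column(s): ", paste(miss, collapse = ", "))
  coords <- as.matrix(coords)
  if (length(coords) == 0L) coords <- matrix(numeric(0), 0, 3)
  if (ncol(coords) != 3L)
    stop("coordinates must be an N x 3 matrix")
  if (nrow(coords) != nrow(atoms))
    stop("coordinate row count (", nrow(coords),
         ") does not match atom count (", nrow(atoms), ")")
  atoms$resid <- as.integer(atoms$resid)
  rownames(atoms) <- NULL
  dimnames(coords) <- NULL
  structure(list(atoms = atoms, coords = coords), class = "Structure")
}

#' @export
print.Structure <- function(x, ...) {
  cat("Structure:", nrow(x$atoms), "atoms,",
      length(unique(paste(x$atoms$chain, x$atoms$resid))), "residues,",
      length(unique(x$atoms$chain)), "chain(s)\n")
  invisible(x)
}

#' Number of atoms in a Structure
#' @param x A `Structure`.
#' @return Integer atom count.
#' @export
n_atoms <- function(x) nrow(x$atoms)

# Guess element from a PDB atom name when the element column is blank.
guess_element <- function(atom_name) {
  nm <- gsub("[^A-Za-z]", "", atom_name)
  two <- toupper(substr(nm, 1, 2))
  ifelse(two %in% c("CL", "BR", "NA", "MG", "ZN", "FE", "CA") &
           nchar(atom_name) == 2 & !grepl("^[0-9]", atom_name) &
           atom_name %in% c("CL", "BR", "NA", "MG", "ZN", "FE"),
         two, toupper(substr(nm, 1, 1)))
}

#' Read a PDB file into a Structure
#'
#' Parses ATOM/HETATM records (via bio3d) into the package's Structure
#' representation. Coordinates are in Angstrom. Insertion codes are rejected
#' with an error rather than silently merged, because residue lookup is by
#' (chain, residue number) only. Alternate locations are not handled.
#'
#' @param path Path to a PDB file.
#' @return A `Structure`.
#' @export
#' @examples
#' pdb <- tempfile(fileext = ".pdb")
#' writeLines(c(
#'  "ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00           C",
#'  "END"), pdb)
#' read_pdb(pdb)
read_pdb <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) {
                    stop("PDB parse error in '", path, "': ",
                         conditionMessage(e), call. = FALSE)
                  })
  a <- pdb$atom
  if (is.null(a) || nrow(a) == 0L) stop("empty input: no ATOM/HETATM records in ", path)
  ins <- a$insert
  bad <- !is.na(ins) & nzchar(trimws(ins))
  if (any(bad)) {
    stop("insertion codes are not supported (first at residue ",
         a$resno[which(bad)[1]], ", chain ", a$chain[which(bad)[1]],
         "); renumber the structure")
  }
  elem <- trimws(a$elesy %||% "")
  if (length(elem) == 0L || all(!nzchar(elem))) elem <- guess_element(a$elety)
  elem[!nzchar(elem)] <- guess_element(a$elety[!nzchar(elem)])
  chain <- a$chain
  chain[is.na(chain) | !nzchar(chain)] <- " "
  atoms <- data.frame(
    atom_name = trimws(a$elety),
    element   = toupper(trimws(elem)),
    resid     = as.integer(a$resno),
    resname   = trimws(a$resid),
    chain     = chain,
    stringsAsFactors = FALSE
  )
  new_structure(atoms, cbind(a$x, a$y, a$z))
}

#' Write a Structure to a PDB file
#'
#' Fixed-column ATOM records, one per atom, coordinates in Angstrom.
#'
#' @param x A `Structure`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_pdb <- function(x, path) {
  stopifnot(inherits(x, "Structure"))
  a <- x$atoms
  xyz <- x$coords
  nm <- a$atom_name
  # PDB atom-name column convention: names of <4 chars start in column 14
  nm_fmt <- ifelse(nchar(nm) >= 4, substr(nm, 1, 4), sprintf(" %-3s", nm))
  lines <- sprintf(
    "ATOM  %5d %4s %-4s%1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    seq_len(nrow(a)) %% 100000, nm_fmt, substr(a$resname, 1, 4),
    substr(a$chain, 1, 1), a$resid %% 10000,
    xyz[, 1], xyz[, 2], xyz[, 3], substr(a$element, 1, 2))
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Read a GRO file (single frame) into a Structure
#'
#' GROMACS .gro coordinates are in nm and are converted to Angstrom at this
#' boundary. Only the first frame of a multi-frame file is read. Chain IDs
#' are not part of the format; all atoms get chain "A".
#'
#' @param path Path to a .gro file.
#' @return A `Structure` with attribute `box` (Angstrom edge lengths).
#' @export
read_gro <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 3L) stop("truncated GRO file: ", path)
  n <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(n) || n <= 0L) stop("GRO parse error at line 2: bad atom count")
  if (length(lines) < 2L + n + 1L) stop("truncated GRO file: expected ", n, " atoms")
  rec <- lines[3:(2 + n)]
  resid   <- as.integer(substr(rec, 1, 5))
  resname <- trimws(substr(rec, 6, 10))
  aname   <- trimws(substr(rec, 11, 15))
  xs <- as.numeric(substr(rec, 21, 28))
  ys <- as.numeric(substr(rec, 29, 36))
  zs <- as.numeric(substr(rec, 37, 44))
  if (anyNA(c(xs, ys, zs)))
    stop("GRO parse error: non-numeric coordinate near line ",
         2 + which(is.na(xs + ys + zs))[1])
  boxv <- suppressWarnings(as.numeric(strsplit(trimws(lines[3 + n]), "\\s+")[[1]]))
  if (length(boxv) > 3 && any(abs(boxv[-(1:3)]) > 1e-9))
    stop("triclinic boxes are not supported")
  atoms <- data.frame(
    atom_name = aname, element = guess_element(aname),
    resid = resid, resname = resname, chain = "A",
    stringsAsFactors = FALSE)
  out <- new_structure(atoms, cbind(xs, ys, zs) * 10)  # nm -> Angstrom
  attr(out, "box") <- boxv[1:3] * 10
  out
}
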