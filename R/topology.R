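# Core containers: Topology (static atom metadata) and Trajectory (a stack of
# coordinate frames at a uniform interval).  Coordinates are Angstrom, times
# picoseconds, angles degrees, throughout the package.

# PDB v2 legacy atom names mapped onto v3 conventions.
.name_normalization <- c(
  "O1P" = "OP1", "O2P" = "OP2", "O3P" = "OP3",
  "C5M" = "C7", "1H2" = "H21", "2H2" = "H22"
)

normalize_atom_name <- function(name) {
  name <- gsub("*", "'", trimws(name), fixed = TRUE)
  hit <- match(name, names(.name_normalization))
  name[!is.na(hit)] <- .name_normalization[hit[!is.na(hit)]]
  name
}

.residue_key <- function(chain, resno, insert) {
  insert <- ifelse(is.na(insert) | insert == " ", "", insert)
  chain <- ifelse(is.na(chain) | chain == " ", "", chain)
  paste0(chain, ":", resno, insert)
}

#' Construct a Topology from atom metadata
#'
#' A `Topology` holds the ordered atom table of a structure and the residue
#' hierarchy derived from it.  Residue identity is the triple
#' (chain, residue number, insertion code), with 1-based residue numbers as
#' written in PDB files.
#'
#' @param atoms data.frame with columns `name`, `element`, `chain`, `resno`,
#'   `resname` and optionally `insert` (insertion code) and `eleno`
#'   (serial number).  One row per atom, in file order.
#' @return An object of class `Topology` with components `atoms` (the
#'   augmented atom table, including a `reskey` residue identifier) and
#'   `residues` (one row per residue, in order of first appearance).
#' @export
topology <- function(atoms) {
  stopifnot(is.data.frame(atoms), nrow(atoms) > 0L)
  needed <- c("name", "element", "chain", "resno", "resname")
  missing <- setdiff(needed, names(atoms))
  if (length(missing) > 0L)
    stop("atom table lacks column(s): ", paste(missing, collapse = ", "))
  if (is.null(atoms$insert)) atoms$insert <- ""
  if (is.null(atoms$eleno)) atoms$eleno <- seq_len(nrow(atoms))
  atoms$name <- normalize_atom_name(atoms$name)
  if (any(!nzchar(atoms$name))) stop("atom with empty name")
  atoms$reskey <- .residue_key(atoms$chain, atoms$resno, atoms$insert)
  atoms$index <- seq_len(nrow(atoms))
  first <- !duplicated(atoms$reskey)
  residues <- atoms[first, c("chain", "resno", "insert", "resname", "reskey")]
  rownames(residues) <- NULL
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, residues = residues), class = "Topology")
}

#' @export
print.Topology <- function(x, ...) {
  cat(sprintf("Topology: %d atoms, %d residues, %d chain(s)\n",
              nrow(x$atoms), nrow(x$residues),
              length(unique(x$residues$chain))))
  invisible(x)
}

n_atoms <- function(topology) nrow(topology$atoms)

# Pre-scan of a PDB text for the error contracts the reader must honour:
# malformed ATOM records are reported with their line number, and per-MODEL
# atom counts are returned so trajectory loading can name a defective model.
.scan_pdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(is_atom)) stop("no ATOM/HETATM records in '", path, "'")
  atom_lines <- which(is_atom)
  for (i in atom_lines) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stop("malformed ATOM record at line ", i, ": record too short")
    coords <- suppressWarnings(as.numeric(c(
      substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54))))
    resno <- suppressWarnings(as.integer(substr(ln, 23, 26)))
    if (anyNA(coords) || is.na(resno))
      stop("malformed ATOM record at line ", i, ": unparseable field")
  }
  model_starts <- which(rec == "MODEL ")
  if (length(model_starts) == 0L) {
    counts <- length(atom_lines)
    model_no <- 1L
  } else {
    ends <- c(model_starts[-1L] - 1L, length(lines))
    counts <- vapply(seq_along(model_starts), function(k)
      sum(atom_lines > model_starts[k] & atom_lines <= ends[k]), integer(1))
    model_no <- suppressWarnings(as.integer(substr(lines[model_starts], 7, 14)))
    model_no[is.na(model_no)] <- seq_along(model_starts)[is.na(model_no)]
  }
  list(n_models = length(counts), counts = counts, model_no = model_no)
}

.topology_from_bio3d <- function(pdb) {
  at <- pdb$atom
  element <- trimws(at$elesy)
  if (is.null(element)) element <- rep(NA_character_, nrow(at))
  guess <- is.na(element) | !nzchar(element)
  element[guess] <- substr(gsub("^[0-9']+", "", trimws(at$elety[guess])), 1, 1)
  topology(data.frame(
    name = at$elety, element = element, chain = at$chain,
    resno = at$resno, resname = trimws(at$resid),
    insert = ifelse(is.na(at$insert), "", at$insert),
    eleno = at$eleno, stringsAsFactors = FALSE))
}

#' Read a Topology from a PDB file
#'
#' Parses ATOM/HETATM records (first model of a multi-model file), preserving
#' the chain / residue-number / insertion-code hierarchy.  Legacy atom names
#' are normalised to PDB v3 (O1P becomes OP1, `*` becomes `'`).
#'
#' @param path path to a PDB file.
#' @param format only `"pdb"` is supported.
#' @return A [topology()] object.
#' @export
load_topology <- function(path, format = "pdb") {
  format <- match.arg(format, "pdb")
  if (!file.exists(path)) stop("file not found: ", path)
  .scan_pdb(path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  .topology_from_bio3d(pdb)
}

#' Construct a Trajectory
#'
#' @param topology a [topology()] object.
#' @param coords numeric array of dimension `n_frames x n_atoms x 3`, in
#'   Angstrom.
#' @param dt frame interval in picoseconds (> 0); PDB files do not carry it,
#'   so it is always user-supplied.
#' @param box optional per-frame orthorhombic box lengths, `n_frames x 3`
#'   matrix in Angstrom; enables minimum-image distances downstream.
#' @return An object of class `Trajectory`.
#' @export
trajectory <- function(topology, coords, dt, box = NULL) {
  stopifnot(inherits(topology, "Topology"))
  if (length(dim(coords)) != 3L || dim(coords)[3] != 3L)
    stop("coords must be an n_frames x n_atoms x 3 array")
  if (dim(coords)[2] != n_atoms(topology))
    stop("coords atom count (", dim(coords)[2],
         ") does not match topology (", n_atoms(topology), ")")
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("dt must be a single positive number of picoseconds")
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  if (!is.null(box)) {
    box <- matrix(box, ncol = 3)
    if (nrow(box) == 1L) box <- box[rep(1L, dim(coords)[1]), , drop = FALSE]
    stopifnot(nrow(box) == dim(coords)[1])
  }
  structure(list(topology = topology, coords = coords, dt = dt, box = box),
            class = "Trajectory")
}

#' @export
print.Trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d frames x %d atoms, dt = %g ps (%.3f ns total)\n",
              n_frames(x), n_atoms(x$topology), x$dt,
              n_frames(x) * x$dt / 1000))
  invisible(x)
}

#' Number of frames in a Trajectory
#' @param trajectory a [trajectory()] object.
#' @export
n_frames <- function(trajectory) dim(trajectory$coords)[1]

#' Read a multi-model PDB file as a Trajectory
#'
#' Frames are ordered by MODEL number.  Every model must contain the same
#' atoms as the topology; a mismatch is reported with the offending model
#' number.
#'
#' @param path path to a (possibly multi-model) PDB file.
#' @param topology optional [topology()]; parsed from the file if omitted.
#' @inheritParams trajectory
#' @return A [trajectory()] object with one frame per MODEL record (one frame
#'   for a plain single-structure file).
#' @export
load_trajectory <- function(path, topology = NULL, dt = 1) {
  if (!is.numeric(dt) || dt <= 0) stop("dt must be > 0 ps")
  scan <- .scan_pdb(path)
  if (is.null(topology)) topology <- load_topology(path)
  nat <- n_atoms(topology)
  bad <- which(scan$counts != nat)
  if (length(bad) > 0L)
    stop(sprintf("model %d has %d atoms, topology has %d",
                 scan$model_no[bad[1]], scan$counts[bad[1]], nat))
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nf <- nrow(xyz)
  coords <- aperm(array(t(xyz), dim = c(3, nat, nf)), c(3, 2, 1))
  trajectory(topology, coords, dt = dt)
}

#' Write a Trajectory as a multi-model PDB file
#'
#' Round-trips coordinates at the PDB fixed-point precision of 0.001 A.
#'
#' @param trajectory a [trajectory()] object.
#' @param path output path.
#' @export
write_trajectory <- function(trajectory, path) {
  top <- trajectory$topology
  nf <- n_frames(trajectory)
  nat <- n_atoms(top)
  xyz <- matrix(aperm(trajectory$coords, c(3, 2, 1)), nrow = nf, byrow = TRUE)
  bio3d::write.pdb(
    pdb = NULL, file = path, xyz = xyz,
    type = rep("ATOM", nat),
    eleno = top$atoms$eleno, elety = top$atoms$name,
    resid = top$atoms$resname, chain = top$atoms$chain,
    resno = top$atoms$resno,
    insert = ifelse(nzchar(top$atoms$insert), top$atoms$insert, NA),
    elesy = top$atoms$element)
  invisible(path)
}

# Coordinates of one frame as an n_atoms x 3 matrix.
frame_coords <- function(trajectory, frame) {
  trajectory$coords[frame, , , drop = TRUE]
}

#' Summarise a structure file as JSON
#'
#' Convenience used by the analysis scripts: atom, residue and frame counts
#' of a (multi-model) PDB file.
#'
#' @param path path to a PDB file.
#' @return A list (atoms, residues, chains, frames), invisibly printed as
#'   JSON.
#' @export
structure_info <- function(path) {
  scan <- .scan_pdb(path)
  top <- load_topology(path)
  info <- list(atoms = n_atoms(top), residues = nrow(top$residues),
               chains = length(unique(top$residues$chain)),
               frames = scan$n_models)
  cat(jsonlite::toJSON(info, auto_unbox = TRUE), "\n")
  invisible(info)
}
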