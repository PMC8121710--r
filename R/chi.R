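# Glycosidic torsion computation.

.cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Signed dihedral angle over trajectory frames
#'
#' Standard atan2 construction on the three bond vectors; 0 for an eclipsed
#' (cis) arrangement, 180 for trans.
#'
#' @param trajectory a [trajectory()] object.
#' @param idx integer vector of four atom indices defining the torsion.
#' @param wrap if `TRUE` (default) wrap angles to `[0, 360)`, otherwise
#'   return the signed angle in `(-180, 180]`.
#' @return Numeric vector of angles in degrees, one per frame.
#' @export
dihedral_series <- function(trajectory, idx, wrap = TRUE) {
  stopifnot(length(idx) == 4L)
  p <- lapply(idx, function(i) trajectory$coords[, i, , drop = FALSE])
  p <- lapply(p, function(x) matrix(x, ncol = 3))
  b1 <- p[[2]] - p[[1]]
  b2 <- p[[3]] - p[[2]]
  b3 <- p[[4]] - p[[3]]
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  b2n <- b2 / sqrt(rowSums(b2^2))
  m1 <- .cross3(n1, b2n)
  x <- rowSums(n1 * n2)
  y <- -rowSums(m1 * n2)
  ang <- atan2(y, x) * 180 / pi
  if (wrap) ang %% 360 else ang
}

.is_purine <- function(topology, reskey) {
  at <- topology$atoms
  any(at$reskey == reskey & at$name == "N9")
}

#' Compute the glycosidic chi torsion of a nucleotide
#'
#' The chi dihedral is O4'-C1'-N9-C4 for purines and O4'-C1'-N1-C2 for
#' pyrimidines (IUPAC convention); with it, syn conformers sit near 60 deg
#' and anti conformers near 240 deg.  Purine/pyrimidine is decided by the
#' presence of an N9 atom in the residue.
#'
#' @param trajectory a [trajectory()] object.
#' @param resno residue number of the nucleotide.
#' @param chain optional chain id disambiguating the residue.
#' @return An `AngleSeries`: list with `values` (degrees in `[0, 360)`, one
#'   per frame), `dt` (ps) and `residue` (the residue key).
#' @export
compute_chi <- function(trajectory, resno, chain = NULL) {
  top <- trajectory$topology
  hit <- top$residues$resno == resno
  if (!is.null(chain)) hit <- hit & top$residues$chain == chain
  if (!any(hit)) stop("no residue ", resno, " in topology")
  reskey <- top$residues$reskey[which(hit)[1]]
  rchain <- top$residues$chain[which(hit)[1]]
  quad <- if (.is_purine(top, reskey)) c("O4'", "C1'", "N9", "C4")
          else c("O4'", "C1'", "N1", "C2")
  idx <- vapply(quad, function(nm) {
    i <- which(top$atoms$reskey == reskey & top$atoms$name == nm)
    if (length(i) != 1L)
      stop("residue ", reskey, " lacks chi-defining atom ", nm)
    i
  }, integer(1))
  structure(list(values = dihedral_series(trajectory, idx),
                 dt = trajectory$dt,
                 residue = reskey, chain = rchain, resno = resno),
            class = "AngleSeries")
}

#' Build an AngleSeries from raw values
#'
#' Mostly used with synthetic chi traces; values are wrapped to `[0, 360)`.
#'
#' @param values angles in degrees.
#' @param dt frame interval in ps.
#' @param residue optional residue label.
#' @export
angle_series <- function(values, dt, residue = NA_character_) {
  stopifnot(all(is.finite(values)), dt > 0)
  structure(list(values = values %% 360, dt = dt, residue = residue),
            class = "AngleSeries")
}
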