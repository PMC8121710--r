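# HBfix: a structure-specific pairwise bias that stabilises chosen native
# hydrogen bonds by a constant eta inside the bonding distance and ramps
# linearly to zero over a short window, leaving all other geometries
# untouched.  Only evaluation and reporting live here; nothing is fed back
# into an MD engine.

#' HBfix parameters
#'
#' @param eta stabilisation magnitude in kcal/mol (> 0, default 1.0; the
#'   common "mild" setting, with 2.0 used as a stronger control).
#' @param r_full donor-acceptor distance (A) below which the full
#'   stabilisation applies (default 3.0).
#' @param r_off distance (A) beyond which the bias vanishes (default 4.0).
#' @return An `HBfixParams` list.
#' @export
hbfix_params <- function(eta = 1.0, r_full = 3.0, r_off = 4.0) {
  if (!(eta > 0)) stop("eta must be > 0 kcal/mol")
  if (!(r_full > 0 && r_off > r_full))
    stop("need 0 < r_full < r_off")
  structure(list(eta = eta, r_full = r_full, r_off = r_off),
            class = "HBfixParams")
}

#' HBfix energy
#'
#' Flat well of depth `-eta` up to `r_full`, linear ramp to 0 at `r_off`,
#' zero beyond; continuous everywhere (C0 only, with kinks at the two window
#' edges).
#'
#' @param r donor-acceptor distance(s) in Angstrom (>= 0); vectorised.
#' @param params an [hbfix_params()] object.
#' @return Energy in kcal/mol (non-positive).
#' @export
hbfix_energy <- function(r, params = hbfix_params()) {
  stopifnot(inherits(params, "HBfixParams"), all(r >= 0))
  ramp <- -params$eta * (params$r_off - r) / (params$r_off - params$r_full)
  ifelse(r <= params$r_full, -params$eta,
         ifelse(r < params$r_off, ramp, 0))
}

#' HBfix radial force
#'
#' The radial force component `-dU/dr`: zero on the flat well and outside
#' the window, and the constant `-eta / (r_off - r_full)` (attractive,
#' pulling the pair inward) on the ramp.  The potential is only C0, so at
#' the two kink points the ramp-side value is reported.
#'
#' @inheritParams hbfix_energy
#' @return Force in kcal/mol/A; negative values pull the atoms together.
#' @export
hbfix_force <- function(r, params = hbfix_params()) {
  stopifnot(inherits(params, "HBfixParams"), all(r >= 0))
  slope <- -params$eta / (params$r_off - params$r_full)
  ifelse(r >= params$r_full & r <= params$r_off, slope, 0)
}

#' Define an HBfix pair
#'
#' @param atom_a,atom_b atom indices of the biased pair (distinct).
#' @param params per-pair [hbfix_params()].
#' @param label pair label for reports, e.g. `"K31(N)-A13(OP2)"`.
#' @export
hbfix_pair <- function(atom_a, atom_b, params = hbfix_params(), label = "") {
  if (atom_a == atom_b) stop("HBfix pair atoms must differ")
  structure(list(atom_a = atom_a, atom_b = atom_b, params = params,
                 label = label), class = "HBfixPair")
}

#' Per-frame total HBfix bias energy of a trajectory
#'
#' @param trajectory a [trajectory()] object.
#' @param pairs list of [hbfix_pair()] objects.
#' @return List with `per_frame` (kcal/mol, one per frame), `per_pair`
#'   (n_frames x n_pairs matrix) and `summary` (mean/min/max).
#' @export
trajectory_bias_energy <- function(trajectory, pairs) {
  stopifnot(length(pairs) > 0L,
            all(vapply(pairs, inherits, logical(1), "HBfixPair")))
  nat <- n_atoms(trajectory$topology)
  per_pair <- vapply(pairs, function(p) {
    if (p$atom_a > nat || p$atom_b > nat)
      stop("HBfix pair '", p$label, "' references a missing atom")
    hbfix_energy(distance_series(trajectory, p$atom_a, p$atom_b), p$params)
  }, numeric(n_frames(trajectory)))
  per_pair <- matrix(per_pair, nrow = n_frames(trajectory))
  per_frame <- rowSums(per_pair)
  list(per_frame = per_frame, per_pair = per_pair,
       summary = c(mean = mean(per_frame), min = min(per_frame),
                   max = max(per_frame)))
}

#' Export HBfix pairs as flat-well restraint definitions
#'
#' Writes a generic NMR-style distance-restraint text block per pair
#' (atom addresses, well edges, force-constant surrogate from the ramp
#' slope) so the bias can be carried into restraint-capable tools.
#'
#' @param topology a [topology()] object, used to render atom addresses.
#' @param pairs list of [hbfix_pair()] objects.
#' @param path output file path.
#' @export
write_restraints <- function(topology, pairs, path) {
  render <- function(i) {
    a <- topology$atoms[i, ]
    sprintf("%s %d %s", a$chain, a$resno, a$name)
  }
  lines <- unlist(lapply(pairs, function(p) {
    c(sprintf("restraint flat_well %s", p$label),
      sprintf("  atom_a %s", render(p$atom_a)),
      sprintf("  atom_b %s", render(p$atom_b)),
      sprintf("  r_full %.3f", p$params$r_full),
      sprintf("  r_off  %.3f", p$params$r_off),
      sprintf("  depth_kcal_mol %.3f", p$params$eta),
      sprintf("  ramp_slope_kcal_mol_A %.3f",
              p$params$eta / (p$params$r_off - p$params$r_full)),
      "end")
  }))
  writeLines(lines, path)
  invisible(path)
}
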