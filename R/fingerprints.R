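# Per-frame geometric detection of interface interactions: hydrogen bonds,
# water and ion bridges, guanine 4BPh base-phosphate contacts, and vdW
# contacts.  All detectors return an InteractionSeries (one boolean per
# frame) so occupancies and lifetimes come from one aggregator.
#
# Distances use the minimum-image convention when the trajectory carries an
# orthorhombic box, plain Euclidean distance otherwise.

.atom_xyz <- function(trajectory, i) {
  matrix(trajectory$coords[, i, , drop = FALSE], ncol = 3)
}

.min_image <- function(d, box) {
  if (is.null(box)) return(d)
  d - box * round(d / box)
}

#' Per-frame distance between two atoms
#'
#' @param trajectory a [trajectory()] object.
#' @param i,j atom indices (see [atom_index()]).
#' @return Numeric vector of distances in Angstrom, one per frame
#'   (minimum-image when the trajectory has a periodic box).
#' @export
distance_series <- function(trajectory, i, j) {
  d <- .min_image(.atom_xyz(trajectory, j) - .atom_xyz(trajectory, i),
                  trajectory$box)
  sqrt(rowSums(d^2))
}

# Angle (deg) at vertex h between a and b, per frame.
.angle_series <- function(trajectory, a, h, b) {
  v1 <- .min_image(.atom_xyz(trajectory, a) - .atom_xyz(trajectory, h),
                   trajectory$box)
  v2 <- .min_image(.atom_xyz(trajectory, b) - .atom_xyz(trajectory, h),
                   trajectory$box)
  cosang <- rowSums(v1 * v2) / (sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2)))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' Build an InteractionSeries
#' @param present logical vector, one per frame.
#' @param dt frame interval, ps.
#' @param label interaction label, e.g. `"Q33(N)-A13(N7)"`.
#' @export
interaction_series <- function(present, dt, label = "") {
  stopifnot(is.logical(present), dt > 0)
  structure(list(present = present, dt = dt, label = label),
            class = "InteractionSeries")
}

#' Detect a hydrogen bond per frame
#'
#' Present when the donor-acceptor distance is at most `dist_cutoff` and the
#' donor-hydrogen-acceptor angle is at least `angle_cutoff` (both boundaries
#' closed).  Without a hydrogen atom the detector runs in distance-only mode
#' and says so in the returned object.
#'
#' @param trajectory a [trajectory()] object.
#' @param donor,acceptor heavy-atom indices.
#' @param hydrogen donor hydrogen index, or `NULL` for distance-only mode.
#' @param dist_cutoff donor-acceptor cutoff in Angstrom (default 3.5).
#' @param angle_cutoff D-H-A cutoff in degrees (default 120).
#' @param label interaction label carried into reports.
#' @return An [interaction_series()]; attribute `distance_only` records the
#'   mode.
#' @export
detect_hbond <- function(trajectory, donor, acceptor, hydrogen = NULL,
                         dist_cutoff = 3.5, angle_cutoff = 120, label = "") {
  stopifnot(dist_cutoff > 0, angle_cutoff > 0, angle_cutoff <= 180)
  ok <- distance_series(trajectory, donor, acceptor) <= dist_cutoff
  distance_only <- is.null(hydrogen)
  if (!distance_only) {
    if (length(hydrogen) != 1L || is.na(hydrogen) ||
        hydrogen < 1L || hydrogen > n_atoms(trajectory$topology))
      stop("hydrogen atom index is missing or invalid")
    ok <- ok &
      .angle_series(trajectory, donor, hydrogen, acceptor) >= angle_cutoff
  }
  out <- interaction_series(ok, trajectory$dt, label)
  attr(out, "distance_only") <- distance_only
  out
}

#' Detect a single-water bridge per frame
#'
#' Present when one water oxygen simultaneously satisfies the hydrogen-bond
#' criterion with both solute atoms.  When the topology carries no water
#' hydrogens the criterion is distance-only (O...X at most `dist_cutoff`);
#' with hydrogens present, at least one water hydrogen must also satisfy the
#' angle cutoff towards each partner.
#'
#' @param trajectory a [trajectory()] object.
#' @param atom_a,atom_b solute atom indices being bridged.
#' @param waters `AtomSelection` (or indices) of water oxygen atoms.
#' @inheritParams detect_hbond
#' @export
detect_water_bridge <- function(trajectory, atom_a, atom_b, waters,
                                dist_cutoff = 3.5, angle_cutoff = 120,
                                label = "") {
  nf <- n_frames(trajectory)
  if (length(waters) == 0L) {
    warning("empty water selection; water bridge reported absent")
    return(interaction_series(rep(FALSE, nf), trajectory$dt, label))
  }
  top <- trajectory$topology
  ok <- rep(FALSE, nf)
  for (w in as.integer(waters)) {
    near <- distance_series(trajectory, w, atom_a) <= dist_cutoff &
            distance_series(trajectory, w, atom_b) <= dist_cutoff
    hyd <- which(top$atoms$reskey == top$atoms$reskey[w] &
                 toupper(top$atoms$element) == "H")
    if (length(hyd) > 0L) {
      ang_ok <- function(target) {
        m <- Reduce(`|`, lapply(hyd, function(h)
          .angle_series(trajectory, w, h, target) >= angle_cutoff))
        m
      }
      near <- near & ang_ok(atom_a) & ang_ok(atom_b)
    }
    ok <- ok | near
  }
  interaction_series(ok, trajectory$dt, label)
}

#' Detect an ion bridge per frame
#'
#' Present when some ion lies within `cutoff` of both partner atoms.
#'
#' @param trajectory a [trajectory()] object.
#' @param ions `AtomSelection` (or indices) of candidate ions.
#' @param atom_a,atom_b bridged atom indices.
#' @param cutoff ion-partner distance cutoff in Angstrom (default 3.5).
#' @param label interaction label.
#' @export
detect_ion_bridge <- function(trajectory, ions, atom_a, atom_b,
                              cutoff = 3.5, label = "") {
  nf <- n_frames(trajectory)
  ok <- rep(FALSE, nf)
  for (ion in as.integer(ions)) {
    ok <- ok | (distance_series(trajectory, ion, atom_a) <= cutoff &
                distance_series(trajectory, ion, atom_b) <= cutoff)
  }
  interaction_series(ok, trajectory$dt, label)
}

.guanine_resnames <- c("G", "GUA", "RG", "DG", "G5", "G3", "RG5", "RG3")

#' Detect a type-4 base-phosphate (4BPh) interaction per frame
#'
#' The guanine-specific 4BPh contact: the base's N1-H1 and N2-H2 donors both
#' hydrogen-bond to the non-bridging phosphate oxygens (OP1/OP2) of the same
#' target phosphate.  By default both donations are required (strict type-4
#' reading); `lenient = TRUE` accepts a single donation.  Hydrogens are used
#' when the topology has them, otherwise each donor is evaluated in
#' distance-only mode.
#'
#' @param trajectory a [trajectory()] object.
#' @param guanine_resno residue number of the donating guanine.
#' @param target_resno residue number carrying the accepting phosphate.
#' @param chain,target_chain optional chain ids.
#' @param lenient accept a single donor instead of both.
#' @inheritParams detect_hbond
#' @export
detect_4bph <- function(trajectory, guanine_resno, target_resno,
                        chain = NULL, target_chain = NULL,
                        dist_cutoff = 3.5, angle_cutoff = 120,
                        lenient = FALSE, label = "") {
  top <- trajectory$topology
  hit <- top$residues$resno == guanine_resno
  if (!is.null(chain)) hit <- hit & top$residues$chain == chain
  if (!any(hit)) stop("no residue ", guanine_resno, " in topology")
  resname <- toupper(top$residues$resname[which(hit)[1]])
  if (!resname %in% .guanine_resnames)
    stop("4BPh is guanine-specific; residue ", guanine_resno,
         " is ", resname)
  donor_idx <- function(nm) atom_index(top, guanine_resno, nm, chain = chain)
  maybe_h <- function(nm) {
    idx <- tryCatch(atom_index(top, guanine_resno, nm, chain = chain),
                    error = function(e) NULL)
    idx
  }
  acc <- lapply(c("OP1", "OP2"), function(nm)
    atom_index(top, target_resno, nm, chain = target_chain))
  donates <- function(donor, hydrogen) {
    Reduce(`|`, lapply(acc, function(a)
      detect_hbond(trajectory, donor, a, hydrogen = hydrogen,
                   dist_cutoff = dist_cutoff,
                   angle_cutoff = angle_cutoff)$present))
  }
  d1 <- donates(donor_idx("N1"), maybe_h("H1"))
  d2 <- donates(donor_idx("N2"), maybe_h("H21"))
  ok <- if (lenient) d1 | d2 else d1 & d2
  interaction_series(ok, trajectory$dt, label)
}

#' Detect a van der Waals contact per frame
#'
#' Present when the minimum heavy-atom pair distance between the two
#' selections is at most `cutoff`.  Hydrogens in either selection are
#' excluded (with a message).
#'
#' @param trajectory a [trajectory()] object.
#' @param sel_a,sel_b `AtomSelection`s (or index vectors).
#' @param cutoff heavy-atom distance cutoff in Angstrom (default 4.5).
#' @param label interaction label.
#' @export
detect_vdw_contact <- function(trajectory, sel_a, sel_b, cutoff = 4.5,
                               label = "") {
  top <- trajectory$topology
  strip_h <- function(sel) {
    sel <- as.integer(sel)
    keep <- toupper(top$atoms$element[sel]) != "H"
    if (!all(keep)) message("hydrogens excluded from vdW contact selection")
    sel[keep]
  }
  a <- strip_h(sel_a)
  b <- strip_h(sel_b)
  if (length(a) == 0L || length(b) == 0L)
    stop("vdW contact needs nonempty heavy-atom selections")
  if (length(intersect(a, b)) > 0L)
    warning("vdW contact selections overlap; zero self-distances included")
  nf <- n_frames(trajectory)
  ok <- logical(nf)
  for (f in seq_len(nf)) {
    xa <- trajectory$coords[f, a, , drop = FALSE]
    xb <- trajectory$coords[f, b, , drop = FALSE]
    dim(xa) <- c(length(a), 3)
    dim(xb) <- c(length(b), 3)
    dmin <- Inf
    for (k in seq_len(length(a))) {
      d <- .min_image(sweep(xb, 2, xa[k, ]), trajectory$box)
      dmin <- min(dmin, sqrt(min(rowSums(d^2))))
    }
    ok[f] <- dmin <= cutoff
  }
  interaction_series(ok, trajectory$dt, label)
}

#' Occupancy and event statistics of an interaction
#'
#' @param series an [interaction_series()].
#' @return List with `fraction` (of frames present), `events` (number of
#'   maximal present-runs), and `mean_lifetime_ps` (mean present-run length
#'   times dt; `NA` when never present).
#' @export
occupancy <- function(series) {
  stopifnot(inherits(series, "InteractionSeries"))
  if (length(series$present) == 0L) stop("empty interaction series")
  r <- rle(series$present)
  on <- r$values
  list(fraction = mean(series$present),
       events = sum(on),
       mean_lifetime_ps = if (any(on)) mean(r$lengths[on]) * series$dt
                          else NA_real_,
       label = series$label)
}

#' State-conditioned distance histogram
#'
#' Splits a per-frame distance series by the conformational state of the
#' frames and histograms each state separately, normalised to unit mass
#' (sum of bin masses = 1 per state).  States with zero frames are omitted
#' rather than zero-filled.
#'
#' @param distances numeric vector of per-frame distances (Angstrom).
#' @param states a `StateSeries` (typically debounced) of the same length.
#' @param bin_width bin width in Angstrom (default 0.1).
#' @return A `StateConditionedHistogram`: list with `breaks` (shared bin
#'   edges) and `masses` (named list, one numeric vector per observed
#'   state).
#' @export
state_conditioned_histogram <- function(distances, states, bin_width = 0.1) {
  stopifnot(inherits(states, "StateSeries"),
            length(distances) == length(states$labels), bin_width > 0)
  lo <- floor(min(distances) / bin_width) * bin_width
  hi <- ceiling(max(distances) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  if (breaks[length(breaks)] < hi) breaks <- c(breaks, hi)
  masses <- list()
  for (s in unique(states$labels)) {
    d <- distances[states$labels == s]
    if (length(d) == 0L) next
    h <- hist(d, breaks = breaks, plot = FALSE, include.lowest = TRUE)
    masses[[s]] <- h$counts / sum(h$counts)
  }
  structure(list(breaks = breaks, masses = masses, bin_width = bin_width),
            class = "StateConditionedHistogram")
}
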