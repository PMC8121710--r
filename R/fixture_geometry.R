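# Coordinate realisation of scheduled fixtures.
#
# Builds a minimal Hfq-like scene: per ARN repeat one adenine nucleotide
# (ribose + phosphate + base) whose glycosidic torsion is set exactly per
# frame, plus partner pseudo-atoms (K31 N/O, G29 O, Q33 N, N28 O, I30
# side-chain carbons, a bridging water and a K+ ion) placed to satisfy or
# violate each scheduled interaction, a 4BPh-capable guanine/phosphate pair,
# and a row of N-pocket sites.  Geometry is idealised, not physical: the
# detectors only consume coordinates and names.

.rodrigues <- function(points, origin, axis, angle_deg) {
  k <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  p <- sweep(points, 2, origin)
  rot <- p * cos(th) +
    t(vapply(seq_len(nrow(p)), function(i)
      c(k[2] * p[i, 3] - k[3] * p[i, 2],
        k[3] * p[i, 1] - k[1] * p[i, 3],
        k[1] * p[i, 2] - k[2] * p[i, 1]), numeric(3))) * sin(th) +
    outer(c(p %*% k), k) * (1 - cos(th))
  sweep(rot, 2, origin, `+`)
}

.unit <- function(v) v / sqrt(sum(v^2))

# Ribose + phosphate template (local coordinates, Angstrom); names follow
# PDB v3.  Ring closure is approximate -- no bonded term ever reads it.
.sugar_template <- function() {
  m <- rbind(
    "C1'" = c(0.00, 0.00, 0.00),
    "O4'" = c(1.42, 0.10, 0.00),
    "C4'" = c(2.20, 1.25, 0.10),
    "C3'" = c(1.40, 2.40, 0.35),
    "C2'" = c(-0.02, 1.80, 0.40),
    "O2'" = c(-0.85, 2.45, 1.25),
    "O3'" = c(1.85, 3.60, 0.60),
    "C5'" = c(3.60, 1.05, 0.30),
    "O5'" = c(4.35, 2.25, 0.20),
    "P"   = c(5.85, 2.30, 0.00),
    "OP1" = c(6.35, 1.15, -0.90),
    "OP2" = c(6.45, 3.60, -0.40))
  colnames(m) <- c("x", "y", "z")
  m
}

# Purine base template in its own plane, N9 at the origin, C4 on +x.
.purine_template <- function(kind = c("A", "G")) {
  kind <- match.arg(kind)
  base <- rbind(
    "N9" = c(0.00, 0.00, 0),
    "C4" = c(1.37, 0.00, 0),
    "C5" = c(2.07, 1.17, 0),
    "N7" = c(1.28, 2.29, 0),
    "C8" = c(0.02, 1.86, 0),
    "N3" = c(2.04, -1.20, 0),
    "C2" = c(3.40, -1.20, 0),
    "N1" = c(4.12, -0.05, 0),
    "C6" = c(3.48, 1.21, 0))
  extra <- if (kind == "A") rbind("N6" = c(4.15, 2.36, 0))
  else rbind("O6" = c(4.15, 2.36, 0),
             "N2" = c(4.10, -2.40, 0),
             "H1" = c(5.13, -0.08, 0),
             "H21" = c(5.11, -2.42, 0),
             "H22" = c(3.58, -3.26, 0))
  m <- rbind(base, extra)
  colnames(m) <- c("x", "y", "z")
  m
}

# Place a nucleotide at `origin` with the base rotated so that the chi
# dihedral (O4'-C1'-N9-C4) equals chi_deg exactly.  Returns a named matrix.
.place_nucleotide <- function(origin, chi_deg, kind = "A") {
  sugar <- sweep(.sugar_template(), 2, origin, `+`)
  c1 <- sugar["C1'", ]
  o4 <- sugar["O4'", ]
  # glycosidic bond direction, away from the ring
  u <- .unit(c(-0.45, -0.95, 0.35))
  n9 <- c1 + 1.47 * u
  # base frame: C4 direction at ~126 deg from the N9->C1' direction
  a1 <- .unit(c1 - n9)
  ref <- if (abs(a1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  p <- .unit(ref - sum(ref * a1) * a1)
  ex <- cos(126 * pi / 180) * a1 + sin(126 * pi / 180) * p
  ey <- .unit(.vcross(a1, ex))
  tmpl <- .purine_template(kind)
  base <- t(apply(tmpl, 1, function(q) n9 + q[1] * ex + q[2] * ey))
  # rotate the rigid base about the glycosidic bond to hit chi exactly
  dih <- .dihedral_one(o4, c1, n9, base["C4", ])
  base <- .rodrigues(base, n9, n9 - c1, chi_deg - dih)
  rbind(sugar, base)
}

# cross product of two length-3 vectors
.vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

.dihedral_one <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- .vcross(b1, b2); n2 <- .vcross(b2, b3)
  m1 <- .vcross(n1, .unit(b2))
  (atan2(-sum(m1 * n2), sum(n1 * n2)) * 180 / pi) %% 360
}

#' Build a geometric fixture schedule
#'
#' Per-frame plan for [realize_coordinates()]: chi values and interaction
#' on/off states for each ARN repeat, N-pocket engagement flags, and the
#' 4BPh schedule.  All logical/numeric vectors must have length `n_frames`;
#' inconsistent lengths raise an error naming the offending fields.
#'
#' @param n_frames number of frames.
#' @param repeats list, one element per ARN repeat, each a list with fields
#'   `chi` (degrees per frame), `water_bridge_on`, `a_pocket_on`,
#'   `ion_bridge_on` (logicals per frame) and `k31_o_dist` (K31(O)-O4'
#'   target distance per frame, Angstrom).
#' @param n_pocket_engaged logical vector, one per N-pocket site (any
#'   number of sites; engagement is static per site).
#' @param bph_on logical per frame: is the guanine 4BPh contact formed.
#' @export
fixture_schedule <- function(n_frames, repeats, n_pocket_engaged, bph_on) {
  fields <- c("chi", "water_bridge_on", "a_pocket_on", "ion_bridge_on",
              "k31_o_dist")
  bad <- character(0)
  for (r in seq_along(repeats)) {
    for (f in fields) {
      v <- repeats[[r]][[f]]
      if (is.null(v) || length(v) != n_frames)
        bad <- c(bad, sprintf("repeat %d: %s", r, f))
    }
  }
  if (length(bph_on) != n_frames) bad <- c(bad, "bph_on")
  if (length(bad) > 0L)
    stop("schedule fields with wrong length (need n_frames = ", n_frames,
         "): ", paste(bad, collapse = ", "))
  structure(list(n_frames = n_frames, repeats = repeats,
                 n_pocket_engaged = as.logical(n_pocket_engaged),
                 bph_on = as.logical(bph_on)),
            class = "FixtureSchedule")
}

#' Realise a schedule as coordinates
#'
#' Builds the topology once and one coordinate frame per scheduled frame.
#' The recomputed chi of every nucleotide equals the scheduled value to well
#' under 0.1 degrees (the base is rotated onto it exactly).  Scheduled-off
#' interactions are realised by displacing the partner atom ~10 A away, so
#' the atom list is constant across frames.
#'
#' @param schedule a [fixture_schedule()].
#' @param dt frame interval in ps attached to the resulting trajectory.
#' @return A [trajectory()].  Residue layout: A nucleotides at resno
#'   1, 4, 7, ... on chain R; an A_R surrogate (O2') at resno 50+i; the 4BPh
#'   guanine at resno 18 and its target phosphate at resno 3 (chain R);
#'   protein pseudo-atoms on chain P at resno 100 i + {27, 28, 29, 30, 31,
#'   33}; waters on chain W, ions on chain I; N-pocket sites at resno 70+i
#'   (chain R) versus I30 carbons on chain P.
#' @export
realize_coordinates <- function(schedule, dt = 10) {
  stopifnot(inherits(schedule, "FixtureSchedule"))
  nrep <- length(schedule$repeats)
  nsite <- length(schedule$n_pocket_engaged)
  nf <- schedule$n_frames

  atoms <- list()
  addr <- function(name, element, chain, resno, resname) {
    atoms[[length(atoms) + 1L]] <<- data.frame(
      name = name, element = element, chain = chain, resno = resno,
      resname = resname, stringsAsFactors = FALSE)
    length(atoms)
  }
  sugar_names <- rownames(.sugar_template())
  a_base_names <- rownames(.purine_template("A"))
  g_names <- c(sugar_names, rownames(.purine_template("G")))

  idx <- list(repeats = vector("list", nrep), sites = vector("list", nsite))
  for (r in seq_len(nrep)) {
    resno <- 3L * r - 2L
    nuc <- vapply(c(sugar_names, a_base_names), function(nm)
      addr(nm, substr(gsub("'", "", nm), 1, 1), "R", resno, "A"), integer(1))
    prot <- function(res, nm, el) addr(nm, el, "P", 100L * r + res, "XXX")
    idx$repeats[[r]] <- list(
      resno = resno, nuc = nuc,
      ar_o2 = addr("O2'", "O", "R", 50L + r, "A"),
      wat_o = addr("O", "O", "W", 500L + r, "HOH"),
      ion = addr("K", "K", "I", 900L + r, "K"),
      k31_n = prot(31L, "N", "N"), k31_o = prot(31L, "O", "O"),
      g29_o = prot(29L, "O", "O"), q33_n = prot(33L, "N", "N"),
      n28_o = prot(28L, "O", "O"), n27_o = prot(27L, "O", "O"))
  }
  for (s in seq_len(nsite)) {
    nuc_c <- vapply(c("C4", "C5", "C6"), function(nm)
      addr(nm, "C", "R", 70L + s, "U"), integer(1))
    i30_c <- vapply(c("CB", "CG1", "CD1"), function(nm)
      addr(nm, "C", "P", 100L * (nrep + s) + 30L, "ILE"), integer(1))
    idx$sites[[s]] <- list(nuc = nuc_c, i30 = i30_c)
  }
  gua <- vapply(g_names, function(nm)
    addr(nm, if (grepl("^H", nm)) "H" else substr(gsub("'", "", nm), 1, 1),
         "R", 18L, "G"), integer(1))
  tgt <- vapply(c("P", "OP1", "OP2"), function(nm)
    addr(nm, substr(nm, 1, 1), "R", 3L, "A"), integer(1))
  idx$gua <- gua
  idx$tgt <- tgt

  top <- topology(do.call(rbind, atoms))
  coords <- array(0, dim = c(nf, n_atoms(top), 3))

  for (f in seq_len(nf)) {
    x <- matrix(0, n_atoms(top), 3)
    for (r in seq_len(nrep)) {
      rp <- schedule$repeats[[r]]
      ix <- idx$repeats[[r]]
      origin <- c(30 * (r - 1), 0, 0)
      nuc <- .place_nucleotide(origin, rp$chi[f], "A")
      x[ix$nuc, ] <- nuc
      o4 <- nuc["O4'", ]; c1 <- nuc["C1'", ]; c4p <- nuc["C4'", ]
      op2 <- nuc["OP2", ]; o2p <- nuc["O2'", ]
      n7 <- nuc["N7", ]; c5b <- nuc["C5", ]
      # hbfix partner K31(N): always in the H-bonding range of OP2
      x[ix$k31_n, ] <- op2 + 2.9 * .unit(op2 - nuc["P", ])
      # K31(O) at the scheduled distance from O4' (Fig-4C-style observable)
      x[ix$k31_o, ] <- o4 + rp$k31_o_dist[f] * .unit(o4 - c4p)
      # A_R surrogate O2' and its hbfix partner G29(O)
      ar <- o2p + 5.6 * .unit(o2p - nuc["C2'", ])
      x[ix$ar_o2, ] <- ar
      x[ix$g29_o, ] <- ar + 2.8 * c(0, 0, 1)
      # water bridge A_A(O2')...W...A_R(O2'): midpoint when on, exiled off
      mid <- (o2p + ar) / 2
      x[ix$wat_o, ] <- if (rp$water_bridge_on[f]) mid else mid + c(0, 12, 0)
      # A-pocket H-bond Q33(N)-A_A(N7)
      dir7 <- .unit(n7 - c5b)
      x[ix$q33_n, ] <- n7 + (if (rp$a_pocket_on[f]) 2.9 else 8.0) * dir7
      # ion bridge: K+ equidistant from two backbone O pseudo-atoms
      nb <- origin + c(8, -8, 4)
      x[ix$n28_o, ] <- nb
      x[ix$n27_o, ] <- nb + c(4, 0, 0)
      kpos <- nb + c(2, sqrt(max(2.9^2 - 4, 0)), 0)
      x[ix$ion, ] <- if (rp$ion_bridge_on[f]) kpos else kpos + c(0, -12, 0)
    }
    for (s in seq_len(nsite)) {
      ix <- idx$sites[[s]]
      origin <- c(30 * (s - 1), 40, 0)
      base_c <- rbind(origin, origin + c(1.4, 0, 0), origin + c(0.7, 1.2, 0))
      x[ix$nuc, ] <- base_c
      off <- if (schedule$n_pocket_engaged[s]) 3.8 else 12.0
      x[ix$i30, ] <- sweep(base_c, 2, c(0, 0, off), `+`)
    }
    # 4BPh unit: guanine fixed, target phosphate placed on (or off) the
    # N1-H1 / N2-H21 donor axes
    gnuc <- .place_nucleotide(c(-40, 0, 0), 240, "G")
    x[idx$gua, ] <- gnuc
    n1 <- gnuc["N1", ]; h1 <- gnuc["H1", ]
    n2 <- gnuc["N2", ]; h21 <- gnuc["H21", ]
    op2 <- n1 + 2.9 * .unit(h1 - n1)
    op1 <- n2 + 3.0 * .unit(h21 - n2)
    p <- (op1 + op2) / 2 + c(0.8, 0, 1.2)
    ph <- rbind(p, op1, op2)
    if (!schedule$bph_on[f]) ph <- sweep(ph, 2, c(10, 0, 0), `+`)
    x[idx$tgt, ] <- ph
    coords[f, , ] <- x
  }
  trajectory(top, coords, dt = dt)
}

# Default geometry schedule: interactions ride on the syn/anti state the way
# the A pocket does in the modelled system -- water bridge, Q33 H-bond and
# ion bridge present in anti, lost in syn; K31(O)-O4' distance 3.0 A (anti)
# vs 4.0 A (syn) with 0.1 A jitter.
.default_geometry_schedule <- function(n_frames, n_repeats = 6,
                                       n_sites = 7, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  repeats <- lapply(seq_len(n_repeats), function(r) {
    # deterministic alternation with repeat-specific phase, plus jitter
    period <- 10 + 4 * r
    st <- rep(rep(c("anti", "syn"), length.out = 2 * ceiling(n_frames)),
              each = period)[seq_len(n_frames)]
    anti <- st == "anti"
    chi <- ifelse(anti, 240, 60) + stats::runif(n_frames, -12, 12)
    list(states = st, chi = chi,
         water_bridge_on = anti, a_pocket_on = anti, ion_bridge_on = anti,
         k31_o_dist = ifelse(anti, 3.0, 4.0) +
           stats::runif(n_frames, -0.1, 0.1))
  })
  fixture_schedule(
    n_frames, repeats,
    n_pocket_engaged = c(rep(TRUE, n_sites - 1L), FALSE),
    bph_on = rep(c(TRUE, FALSE), length.out = n_frames))
}

#' Generate the packaged fixture suite
#'
#' Writes, under `out_dir`:
#' \itemize{
#'   \item `dwell_fixture_chi.csv` + `dwell_fixture_ledger.json`: six ARN
#'     repeats with heterogeneous dwell models (per-residue variability on
#'     the tens-to-hundreds of ns scale), as per-frame chi series.
#'   \item `blip_fixture_chi.csv` + `blip_fixture_ledger.json`: a blip-rich
#'     single-residue process for debounce testing.
#'   \item `crc_fixture_chi.csv` + `crc_fixture_ledger.json`: a
#'     flip-suppressed variant (dwells far exceeding the window, as when a
#'     bound partner sterically blocks the flips).
#'   \item `geometry_fixture.pdb` + `geometry_fixture_ledger.json`: a short
#'     multi-model coordinate fixture realising the scheduled interface
#'     interactions.
#' }
#'
#' @param out_dir output directory (created if needed).
#' @param seed RNG seed; the whole suite is reproducible from it.
#' @param total_ns observation window per residue for the dwell fixtures
#'   (default 5000 ns at `dt_ps = 10`, i.e. 5 us sampled every 10 ps).
#' @param dt_ps frame interval, ps.
#' @param n_frames_geom frames in the coordinate fixture.
#' @return Invisibly, a list of written paths plus the in-memory ledgers.
#' @export
make_fixture_suite <- function(out_dir, seed = 1, total_ns = 5000,
                               dt_ps = 10, n_frames_geom = 60) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  paths <- list()

  dwell_models <- list(
    `1` = dwell_model(300, 20), `4` = dwell_model(150, 90),
    `7` = dwell_model(60, 140), `10` = dwell_model(200, 120),
    `13` = dwell_model(50, 160), `16` = dwell_model(120, 100))
  sim <- lapply(dwell_models, function(m)
    sample_dwell_process(m, total_ns, dt_ps))
  chi <- lapply(sim, function(s) synth_chi_series(s$states)$values)
  chi_df <- as.data.frame(chi, check.names = FALSE)
  names(chi_df) <- paste0("A", names(dwell_models))
  paths$dwell_chi <- file.path(out_dir, "dwell_fixture_chi.csv")
  utils::write.csv(chi_df, paths$dwell_chi, row.names = FALSE)
  dwell_ledger <- lapply(sim, function(s) s$ledger)
  paths$dwell_ledger <- file.path(out_dir, "dwell_fixture_ledger.json")
  jsonlite::write_json(dwell_ledger, paths$dwell_ledger, auto_unbox = TRUE,
                       digits = NA)

  blip <- sample_dwell_process(
    dwell_model(200, 200, blip_rate_per_ns = 0.01, blip_duration_ps = 150),
    total_ns, dt_ps)
  blip_chi <- synth_chi_series(blip$states)
  paths$blip_chi <- file.path(out_dir, "blip_fixture_chi.csv")
  utils::write.csv(data.frame(chi = blip_chi$values), paths$blip_chi,
                   row.names = FALSE)
  paths$blip_ledger <- file.path(out_dir, "blip_fixture_ledger.json")
  jsonlite::write_json(blip$ledger, paths$blip_ledger, auto_unbox = TRUE,
                       digits = NA)

  crc <- lapply(1:6, function(r)
    sample_dwell_process(dwell_model(2000, 50 * total_ns,
                                     distribution = "fixed"),
                         total_ns, dt_ps))
  crc_chi <- as.data.frame(lapply(crc, function(s)
    synth_chi_series(s$states)$values))
  names(crc_chi) <- paste0("A", c(1, 4, 7, 10, 13, 16))
  paths$crc_chi <- file.path(out_dir, "crc_fixture_chi.csv")
  utils::write.csv(crc_chi, paths$crc_chi, row.names = FALSE)
  paths$crc_ledger <- file.path(out_dir, "crc_fixture_ledger.json")
  jsonlite::write_json(lapply(crc, function(s) s$ledger), paths$crc_ledger,
                       auto_unbox = TRUE, digits = NA)

  geom_schedule <- .default_geometry_schedule(n_frames_geom)
  geom <- realize_coordinates(geom_schedule, dt = dt_ps)
  paths$geometry <- file.path(out_dir, "geometry_fixture.pdb")
  write_trajectory(geom, paths$geometry)
  geom_ledger <- list(
    n_frames = n_frames_geom, dt_ps = dt_ps,
    states = lapply(geom_schedule$repeats, `[[`, "states"),
    chi = lapply(geom_schedule$repeats, `[[`, "chi"),
    n_pocket_engaged = geom_schedule$n_pocket_engaged,
    bph_on = geom_schedule$bph_on)
  paths$geometry_ledger <- file.path(out_dir, "geometry_fixture_ledger.json")
  jsonlite::write_json(geom_ledger, paths$geometry_ledger, auto_unbox = TRUE,
                       digits = NA)

  invisible(list(paths = paths, dwell_ledger = dwell_ledger,
                 blip_ledger = blip$ledger, geometry_schedule = geom_schedule))
}
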