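# Geometry helpers for detector tests: single-frame trajectories built from
# explicit coordinates.

hbond_frame <- function(d, angle_deg) {
  # hydrogen at the origin; donor 1 A away on +x; acceptor on a ray at
  # angle_deg from the H->D direction, with its length solved so that the
  # donor-acceptor distance is exactly d
  th <- angle_deg * pi / 180
  L <- cos(th) + sqrt(d^2 - sin(th)^2)
  coords <- array(0, dim = c(1, 3, 3))
  coords[1, 1, ] <- c(1, 0, 0)
  coords[1, 3, ] <- L * c(cos(th), sin(th), 0)
  toy_trajectory(coords, c("N", "H", "O"), c("N", "H", "O"))
}

test_that("hydrogen-bond detector honours both cutoffs with closed
           boundaries", {
  geo <- function(d, ang) {
    t <- hbond_frame(d, ang)
    detect_hbond(t, 1, 3, hydrogen = 2)$present
  }
  expect_true(geo(3.4, 150))
  expect_false(geo(3.6, 180))
  expect_true(geo(2.8, 180))    # ideal linear geometry
  expect_false(geo(3.51, 121))
  expect_false(geo(3.4, 119.9))

  # the distance boundary is inclusive: an exactly representable 3.5 A
  # donor-acceptor separation on the x axis, linear geometry
  coords <- array(0, dim = c(1, 3, 3))
  coords[1, 2, ] <- c(1, 0, 0)
  coords[1, 3, ] <- c(3.5, 0, 0)
  edge <- toy_trajectory(coords, c("N", "H", "O"), c("N", "H", "O"))
  expect_true(detect_hbond(edge, 1, 3, hydrogen = 2)$present)
  coords[1, 3, ] <- c(3.5 + 1e-12, 0, 0)
  expect_false(detect_hbond(toy_trajectory(coords, c("N", "H", "O"),
                                           c("N", "H", "O")),
                            1, 3, hydrogen = 2)$present)
  # near the 120 deg angle boundary the detector and a direct closed-
  # boundary oracle agree on every outcome
  for (ang in c(119.999, 119.9999999, 120, 120.0000001, 120.001)) {
    t <- hbond_frame(3.0, ang)
    dn <- t$coords[1, 1, ]; h <- t$coords[1, 2, ]; ac <- t$coords[1, 3, ]
    v1 <- dn - h; v2 <- ac - h
    a <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
    want <- sqrt(sum((ac - dn)^2)) <= 3.5 && a >= 120
    expect_equal(detect_hbond(t, 1, 3, hydrogen = 2)$present, want)
  }

  # distance-only mode is flagged; hydrogen index must be valid if given
  t <- hbond_frame(3.0, 180)
  expect_true(attr(detect_hbond(t, 1, 3), "distance_only"))
  expect_error(detect_hbond(t, 1, 3, hydrogen = 99), "hydrogen")
})

test_that("hydrogen-bond detection agrees with a direct distance/angle
           oracle on random geometries and is monotone in distance", {
  set.seed(101)
  nf <- 2000
  coords <- array(stats::runif(nf * 3 * 3, 0, 8), dim = c(nf, 3, 3))
  traj <- toy_trajectory(coords, c("N", "H", "O"), c("N", "H", "O"))
  got <- detect_hbond(traj, 1, 3, hydrogen = 2)$present
  want <- vapply(seq_len(nf), function(f) {
    dn <- coords[f, 1, ]; h <- coords[f, 2, ]; ac <- coords[f, 3, ]
    dist_ok <- sqrt(sum((ac - dn)^2)) <= 3.5
    v1 <- dn - h; v2 <- ac - h
    ang <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
    dist_ok && ang >= 120
  }, logical(1))
  expect_identical(got, want)

  # pulling the acceptor towards the donor at fixed angle never breaks a
  # detected bond
  for (ang in c(125, 150, 179)) {
    res <- vapply(seq(4.5, 2.2, by = -0.1), function(d)
      detect_hbond(hbond_frame(d, ang), 1, 3, hydrogen = 2)$present,
      logical(1))
    expect_true(all(diff(as.integer(res)) >= 0))
  }
})

test_that("all detectors are invariant under rigid rotation+translation", {
  set.seed(111)
  sch <- nucleoflip:::.default_geometry_schedule(8, n_repeats = 2,
                                                 n_sites = 2)
  traj <- realize_coordinates(sch, dt = 10)
  top <- traj$topology
  run_all <- function(t) {
    list(
      hb = detect_hbond(t, atom_index(top, 133, "N"),
                        atom_index(top, 1, "N7", chain = "R"))$present,
      wb = detect_water_bridge(t, atom_index(top, 1, "O2'", chain = "R"),
                               atom_index(top, 51, "O2'", chain = "R"),
                               atom_index(top, 501, "O", chain = "W"))$present,
      ib = detect_ion_bridge(t, atom_index(top, 901, "K", chain = "I"),
                             atom_index(top, 128, "O"),
                             atom_index(top, 127, "O"))$present,
      bph = detect_4bph(t, 18, 3, chain = "R", target_chain = "R")$present,
      vdw = detect_vdw_contact(
        t, select_atoms(top, "chain R and resid 71"),
        select_atoms(top, "chain P and resid 430"))$present)
  }
  ref <- run_all(traj)
  for (i in 1:25) expect_identical(run_all(apply_random_rigid(traj)), ref)
})

test_that("water bridge requires one water near both partners", {
  mk <- function(w) {
    coords <- array(0, dim = c(1, 3, 3))
    coords[1, 2, ] <- c(5.6, 0, 0)
    coords[1, 3, ] <- w
    toy_trajectory(coords, c("O2'", "O2'", "O"), c("O", "O", "O"),
                   resno = c(1, 2, 3), resname = c("A", "A", "HOH"))
  }
  # midpoint water: 2.8 A from each partner
  expect_true(detect_water_bridge(mk(c(2.8, 0, 0)), 1, 2, 3)$present)
  # oracle: the bridge is exactly the conjunction of two H-bond detections
  for (w in list(c(2.8, 0, 0), c(5, 3, 0), c(1, 1, 1), c(3.2, 1.2, 0))) {
    t <- mk(w)
    both <- detect_hbond(t, 3, 1)$present && detect_hbond(t, 3, 2)$present
    expect_equal(detect_water_bridge(t, 1, 2, 3)$present, both)
  }
  expect_false(detect_water_bridge(mk(c(5, 5, 5)), 1, 2, 3)$present)
  expect_warning(
    out <- detect_water_bridge(mk(c(2.8, 0, 0)), 1, 2, integer(0)),
    "empty water")
  expect_false(out$present)
})

test_that("ion bridge detection follows the two-sided distance criterion", {
  coords <- array(0, dim = c(1, 3, 3))
  coords[1, 2, ] <- c(4, 0, 0)
  coords[1, 3, ] <- c(2, sqrt(2.9^2 - 4), 0)  # 2.9 A from both oxygens
  traj <- toy_trajectory(coords, c("O", "O", "K"), c("O", "O", "K"),
                         resno = 1:3)
  expect_true(detect_ion_bridge(traj, 3, 1, 2)$present)
  expect_equal(distance_series(traj, 3, 1), 2.9, tolerance = 1e-12)
  far <- traj
  far$coords[1, 3, ] <- c(20, 0, 0)
  expect_false(detect_ion_bridge(far, 3, 1, 2)$present)
  expect_false(detect_ion_bridge(traj, 3, 1, 2, cutoff = 0)$present)
})

test_that("4BPh detection needs both guanine donors on one phosphate and
           rejects non-guanine donors", {
  sch <- nucleoflip:::.default_geometry_schedule(6, n_repeats = 1,
                                                 n_sites = 1)
  sch$bph_on <- rep(c(TRUE, FALSE), 3)
  traj <- realize_coordinates(sch, dt = 10)
  got <- detect_4bph(traj, 18, 3, chain = "R", target_chain = "R")
  expect_identical(got$present, sch$bph_on)

  # 4BPh implies both constituent donor H-bonds
  top <- traj$topology
  n1_hb <- detect_hbond(traj, atom_index(top, 18, "N1"),
                        atom_index(top, 3, "OP2", chain = "R"),
                        hydrogen = atom_index(top, 18, "H1"))$present
  n2_hb <- detect_hbond(traj, atom_index(top, 18, "N2"),
                        atom_index(top, 3, "OP1", chain = "R"),
                        hydrogen = atom_index(top, 18, "H21"))$present
  expect_true(all(got$present <= (n1_hb & n2_hb)))

  # a displaced phosphate breaks the interaction (scheduled-off frames are
  # the 10 A translate), and pyrimidines are refused outright
  expect_error(detect_4bph(traj, 1, 3, chain = "R"), "guanine-specific")
})

test_that("vdW contact uses the minimum heavy-atom distance", {
  mk <- function(gap) {
    coords <- array(0, dim = c(1, 4, 3))
    coords[1, 2, ] <- c(1.5, 0, 0)
    coords[1, 3, ] <- c(1.5 + gap, 0, 0)   # closest pair
    coords[1, 4, ] <- c(10, 10, 10)
    toy_trajectory(coords, c("C1", "C2", "C3", "C4"), rep("C", 4),
                   resno = c(1, 1, 2, 2))
  }
  sel <- function(t, r) select_atoms(t$topology, paste("resid", r))
  t <- mk(4.0)
  expect_true(detect_vdw_contact(t, sel(t, 1), sel(t, 2))$present)
  t <- mk(4.6)
  expect_false(detect_vdw_contact(t, sel(t, 1), sel(t, 2))$present)
  # brute-force oracle over a random cloud
  set.seed(121)
  coords <- array(stats::runif(5 * 6 * 3, 0, 10), dim = c(5, 6, 3))
  t <- toy_trajectory(coords, paste0("C", 1:6), rep("C", 6),
                      resno = c(1, 1, 1, 2, 2, 2))
  got <- detect_vdw_contact(t, sel(t, 1), sel(t, 2))$present
  want <- vapply(1:5, function(f) {
    min(as.matrix(stats::dist(coords[f, , ]))[1:3, 4:6]) <= 4.5
  }, logical(1))
  expect_identical(got, want)
  # identical selections: zero distance, detected, with a warning
  expect_warning(self <- detect_vdw_contact(t, sel(t, 1), sel(t, 1)),
                 "overlap")
  expect_true(all(self$present))
  # hydrogens silently excluded (with a message)
  th <- toy_trajectory(coords, c("C1", "H1", "C3", "C4", "C5", "C6"),
                       c("C", "H", "C", "C", "C", "C"),
                       resno = c(1, 1, 1, 2, 2, 2))
  expect_message(detect_vdw_contact(th, 1:3, 4:6), "hydrogen")
})

test_that("occupancy aggregates fractions, events and lifetimes like an
           independent run scanner", {
  all_true <- interaction_series(rep(TRUE, 50), dt = 10)
  oc <- occupancy(all_true)
  expect_equal(oc$fraction, 1)
  expect_equal(oc$events, 1)
  alt <- interaction_series(rep(c(TRUE, FALSE), 25), dt = 10)
  oc <- occupancy(alt)
  expect_equal(oc$fraction, 0.5)
  expect_equal(oc$mean_lifetime_ps, 10)
  set.seed(131)
  for (i in 1:50) {
    x <- stats::runif(sample(5:500, 1)) < stats::runif(1)
    oc <- occupancy(interaction_series(x, dt = 10))
    want <- run_stats_oracle(x, 10)
    expect_equal(oc$fraction, want$fraction)
    expect_equal(oc$events, want$events)
    expect_equal(oc$mean_lifetime_ps, want$mean_lifetime_ps)
  }
  # complement identity
  x <- stats::runif(200) < 0.3
  expect_equal(occupancy(interaction_series(x, 10))$fraction,
               1 - occupancy(interaction_series(!x, 10))$fraction)
  expect_error(occupancy(interaction_series(logical(0), 10)), "empty")
})

test_that("state-conditioned histograms normalise per state and separate
           bimodal distances", {
  # constant distance: one occupied bin with full mass
  st <- state_series(rep("anti", 100), dt = 10)
  h <- state_conditioned_histogram(rep(3.14, 100), st)
  expect_equal(sum(h$masses$anti), 1, tolerance = 1e-9)
  expect_equal(sum(h$masses$anti > 0), 1)
  expect_null(h$masses$syn)  # zero-frame state omitted, not zero-filled

  set.seed(141)
  labels <- rep(c("anti", "syn"), each = 5000)
  d <- c(stats::rnorm(5000, 3.0, 0.1), stats::rnorm(5000, 4.0, 0.1))
  h <- state_conditioned_histogram(d, state_series(labels, 10))
  mids <- utils::head(h$breaks, -1) + h$bin_width / 2
  expect_equal(mids[which.max(h$masses$anti)], 3.0, tolerance = 0.06)
  expect_equal(mids[which.max(h$masses$syn)], 4.0, tolerance = 0.06)
  expect_equal(sum(h$masses$anti), 1, tolerance = 1e-9)
  expect_equal(sum(h$masses$syn), 1, tolerance = 1e-9)
})
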