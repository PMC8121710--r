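test_that("the dwell process is seeded-deterministic and hits its
           stationary fraction", {
  m <- dwell_model(2, 8)
  a <- sample_dwell_process(m, 1000, 10, seed = 7)
  b <- sample_dwell_process(m, 1000, 10, seed = 7)
  expect_identical(a$states$labels, b$states$labels)
  expect_identical(a$ledger$dwells, b$ledger$dwells)

  long <- sample_dwell_process(m, 5000, 10, seed = 8)
  # floored exponential dwells: stationary syn fraction 2.3/(2.3+8.3)
  expect_lt(abs(mean(long$states$labels == "syn") - 2.3 / 10.6), 0.02)
  expect_lt(abs(long$ledger$syn_fraction -
                  mean(long$states$labels == "syn")), 0.01)
})

test_that("without blips the pipeline recovers the ledger transition count
           exactly", {
  sim <- sample_dwell_process(dwell_model(5, 15), 2000, 10, seed = 17)
  st <- debounce_states(classify_conformer(synth_chi_series(sim$states)),
                        300)
  expect_equal(transition_stats(st)$n_transitions, sim$ledger$n_transitions)
})

test_that("blips are rejected by debouncing and double the raw count", {
  m <- dwell_model(100, 100, blip_rate_per_ns = 0.02,
                   blip_duration_ps = 150)
  sim <- sample_dwell_process(m, 3000, 10, seed = 27)
  expect_gt(sim$ledger$n_blips, 0)
  raw <- state_series(sim$states$labels, 10)
  expect_equal(transition_stats(raw)$n_transitions,
               sim$ledger$n_transitions + 2 * sim$ledger$n_blips)
  deb <- debounce_states(raw, 300)
  expect_equal(transition_stats(deb)$n_transitions,
               sim$ledger$n_transitions)
  # with debouncing off, nothing is removed
  expect_equal(transition_stats(debounce_states(raw, 0))$n_transitions,
               sim$ledger$n_transitions + 2 * sim$ledger$n_blips)

  expect_error(sample_dwell_process(m, 100, dt_ps = 200), "blip")
  expect_error(dwell_model(1, 1, blip_rate_per_ns = 1,
                           blip_duration_ps = 400), "300 ps")
})

test_that("synthetic chi series sit in their wells and re-classify to the
           generating labels", {
  set.seed(37)
  labels <- random_labels(1e5, persist = 0.995)
  states <- state_series(labels, 10)
  # noiseless limit: classification is exact
  tight <- suppressWarnings(chi_well_model(sd = 1e-9))
  chi0 <- synth_chi_series(states, tight, seed = 38)
  expect_identical(classify_conformer(chi0)$labels, labels)
  # default width: recovery at or above 99.9%
  chi <- synth_chi_series(states, seed = 39)
  expect_gte(mean(classify_conformer(chi)$labels == labels), 0.999)
  # per-state circular means within a degree of the wells
  ang <- chi$values[labels == "syn"] * pi / 180
  mean_syn <- atan2(mean(sin(ang)), mean(cos(ang))) * 180 / pi
  expect_lt(abs(mean_syn - 60), 1)
  ang <- chi$values[labels == "anti"] * pi / 180
  mean_anti <- (atan2(mean(sin(ang)), mean(cos(ang))) * 180 / pi) %% 360
  expect_lt(abs(mean_anti - 240), 1)

  expect_error(chi_well_model(mean_syn = 200), "inside")
  expect_warning(chi_well_model(mean_syn = 145, sd = 15), "2 sd")
})

test_that("realised coordinates honour the schedule: exact chi, state-
           coupled interactions, deterministic bytes", {
  sch <- nucleoflip:::.default_geometry_schedule(30, seed = 47)
  traj <- realize_coordinates(sch, dt = 10)
  top <- traj$topology
  for (r in c(1, 4)) {
    resno <- 3 * r - 2
    chi <- compute_chi(traj, resno, chain = "R")
    expect_lt(max(abs(chi$values - sch$repeats[[r]]$chi %% 360)), 0.1)
    wb <- detect_water_bridge(
      traj, atom_index(top, resno, "O2'", chain = "R"),
      atom_index(top, 50 + r, "O2'", chain = "R"),
      atom_index(top, 500 + r, "O", chain = "W"))
    on <- sch$repeats[[r]]$water_bridge_on
    expect_gte(mean(wb$present[on]), 0.99)
    expect_lte(mean(wb$present[!on]), 0.01)
  }
  bph <- detect_4bph(traj, 18, 3, chain = "R", target_chain = "R")
  expect_identical(bph$present, sch$bph_on)

  # byte-identical output for identical seed + config
  f1 <- tempfile(fileext = ".pdb"); f2 <- tempfile(fileext = ".pdb")
  write_trajectory(realize_coordinates(
    nucleoflip:::.default_geometry_schedule(10, seed = 5), 10), f1)
  write_trajectory(realize_coordinates(
    nucleoflip:::.default_geometry_schedule(10, seed = 5), 10), f2)
  expect_identical(readLines(f1), readLines(f2))

  # inconsistent schedules are rejected with the offending fields named
  bad <- sch$repeats
  bad[[2]]$chi <- bad[[2]]$chi[-1]
  expect_error(fixture_schedule(30, bad, sch$n_pocket_engaged, sch$bph_on),
               "repeat 2: chi")
})

test_that("the fixture suite builds, reloads, and its dwell report matches
           the ledger", {
  out <- file.path(tempdir(), "suite_test")
  suite <- suppressWarnings(
    make_fixture_suite(out, seed = 3, total_ns = 150, n_frames_geom = 12))
  for (p in suite$paths) expect_true(file.exists(p))

  chi <- utils::read.csv(suite$paths$dwell_chi, check.names = FALSE)
  expect_equal(nrow(chi), 15000)
  series <- lapply(chi, angle_series, dt = 10)
  rep_df <- dwell_report(series)
  led_counts <- vapply(suite$dwell_ledger, function(l) l$n_transitions,
                       numeric(1))
  expect_equal(rep_df$n_transitions, unname(led_counts))

  # flip-suppressed variant: no transitions within the window
  crc <- jsonlite::read_json(file.path(out, "crc_fixture_ledger.json"))
  expect_true(all(vapply(crc, function(l) l$n_transitions, numeric(1)) == 0))

  geom <- load_trajectory(suite$paths$geometry, dt = 10)
  expect_equal(n_frames(geom), 12L)

  # N-pocket engagement: engaged sites hold the I30 contact, the flipped
  # site does not
  nrep <- length(suite$geometry_schedule$repeats)
  eng <- suite$geometry_schedule$n_pocket_engaged
  occ <- vapply(seq_along(eng), function(s) {
    occupancy(detect_vdw_contact(
      geom, select_atoms(geom$topology, paste("chain R and resid", 70 + s)),
      select_atoms(geom$topology,
                   paste("chain P and resid", 100 * (nrep + s) + 30))))$fraction
  }, numeric(1))
  expect_true(all(occ[eng] >= 0.9))
  expect_true(all(occ[!eng] <= 0.1))
})
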