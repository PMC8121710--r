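test_that("dihedral computation matches identities and an independent
           torsion implementation", {
  # eclipsed and trans arrangements on a single frame
  cis <- array(0, dim = c(1, 4, 3))
  cis[1, 1, ] <- c(1, 1, 0); cis[1, 2, ] <- c(0, 1, 0)
  cis[1, 3, ] <- c(0, 0, 0); cis[1, 4, ] <- c(1, 0, 0)
  trans <- cis
  trans[1, 4, ] <- c(-1, 0, 0)
  traj_cis <- toy_trajectory(cis, c("A1", "A2", "A3", "A4"), rep("C", 4))
  traj_trans <- toy_trajectory(trans, c("A1", "A2", "A3", "A4"), rep("C", 4))
  expect_equal(dihedral_series(traj_cis, 1:4), 0, tolerance = 1e-10)
  expect_equal(dihedral_series(traj_trans, 1:4), 180, tolerance = 1e-10)

  # random geometries vs bio3d's torsion implementation
  set.seed(11)
  nf <- 200
  coords <- array(stats::runif(nf * 4 * 3, -10, 10), dim = c(nf, 4, 3))
  traj <- toy_trajectory(coords, c("A1", "A2", "A3", "A4"), rep("C", 4))
  mine <- dihedral_series(traj, 1:4)
  oracle <- vapply(seq_len(nf), function(f) {
    bio3d::torsion.xyz(as.vector(t(coords[f, , ])), atm.inc = 4)
  }, numeric(1)) %% 360
  expect_equal(mine, unname(oracle), tolerance = 1e-6)
})

test_that("syn/anti windows partition the circle with the documented
           boundary convention", {
  win <- state_windows()
  lab <- function(x) classify_conformer(angle_series(x, 10), win)$labels
  expect_equal(lab(60), "syn")
  expect_equal(lab(240), "anti")
  expect_equal(lab(150), "anti")   # upper syn edge belongs to anti
  expect_equal(lab(330), "syn")    # 330 == -30, lower syn edge
  grid <- seq(0, 359.75, by = 0.25)
  labels <- lab(grid)
  expect_true(all(labels %in% c("syn", "anti")))
  expect_equal(sum(labels == "syn"), sum(grid >= 330 | grid < 150))
})

test_that("debouncing removes sub-threshold excursions and matches the
           brute-force run-merging oracle", {
  # the canonical 200 ps excursion at dt = 10 ps
  s <- state_series(rep(c("anti", "syn", "anti"), c(100, 20, 100)), dt = 10)
  d <- debounce_states(s, 300)
  expect_true(all(d$labels == "anti"))
  expect_equal(transition_stats(d)$n_transitions, 0)

  # min_dwell = 0 is the identity
  set.seed(21)
  raw <- state_series(random_labels(500, persist = 0.8), dt = 10)
  expect_identical(debounce_states(raw, 0)$labels, raw$labels)

  # property: equality with the oracle over random series of many shapes
  for (rep_i in 1:200) {
    n <- sample(10:2000, 1)
    persist <- stats::runif(1, 0.3, 0.99)
    labels <- random_labels(n, persist)
    s <- state_series(labels, dt = 10)
    expect_identical(debounce_states(s, 300)$labels,
                     debounce_oracle(labels, 10, 300))
  }
})

test_that("debouncing is idempotent, monotone in transition count, and
           introduces no foreign state", {
  set.seed(31)
  for (i in 1:50) {
    labels <- random_labels(sample(20:1500, 1), stats::runif(1, 0.4, 0.98))
    s <- state_series(labels, dt = 10)
    d1 <- debounce_states(s, 300)
    d2 <- debounce_states(d1, 300)
    expect_identical(d1$labels, d2$labels)
    expect_lte(transition_stats(d1)$n_transitions,
               transition_stats(s)$n_transitions)
    expect_true(all(unique(d1$labels) %in% unique(labels)))
  }
})

test_that("transition statistics follow their definitions", {
  s <- debounce_states(state_series(
    rep(c("anti", "syn", "anti"), each = 1000), dt = 10), 300)
  st <- transition_stats(s)
  expect_equal(st$n_transitions, 2)
  expect_equal(st$syn_population, 1 / 3)
  expect_equal(st$time_to_first_ns, 10)
  expect_equal(st$mean_lifetime_syn_ns, 10)
  expect_equal(st$mean_lifetime_anti_ns, 10)  # one completed anti run
  expect_equal(st$censored_state, "anti")

  all_anti <- transition_stats(state_series(rep("anti", 100), dt = 10))
  expect_equal(all_anti$n_transitions, 0)
  expect_equal(all_anti$syn_population, 0)
  expect_true(is.na(all_anti$time_to_first_ns))

  # alternating-renewal series with known draws vs hand bookkeeping
  set.seed(41)
  runs_ns <- c(5, 2, 8, 1, 6, 3)  # anti, syn, anti, syn, anti, syn(censored)
  labels <- rep(rep(c("anti", "syn"), 3), runs_ns * 100)  # dt = 10 ps
  st <- transition_stats(state_series(labels, dt = 10))
  expect_equal(st$n_transitions, 5)
  expect_equal(st$mean_lifetime_anti_ns, mean(c(5, 8, 6)))
  expect_equal(st$mean_lifetime_syn_ns, mean(c(2, 1)))  # final syn censored
  expect_equal(st$mean_lifetime_syn_censored_ns, mean(c(2, 1, 3)))
  expect_equal(st$syn_population, sum(c(2, 1, 3)) / sum(runs_ns))

  expect_error(transition_stats(state_series(character(0), dt = 10)),
               "empty|length")
})

test_that("statistics are invariant under time reversal", {
  set.seed(51)
  for (i in 1:20) {
    labels <- random_labels(sample(100:2000, 1), 0.97)
    fwd <- transition_stats(state_series(labels, dt = 10))
    rev_ <- transition_stats(state_series(rev(labels), dt = 10))
    expect_equal(fwd$n_transitions, rev_$n_transitions)
    expect_equal(fwd$syn_population, rev_$syn_population)
  }
})

test_that("dwell report recovers scheduled flip counts and respects the
           absent-value convention", {
  set.seed(61)
  models <- list(`1` = dwell_model(20, 30, distribution = "fixed"),
                 `4` = dwell_model(50, 50, distribution = "fixed"),
                 `7` = dwell_model(5000, 5000, distribution = "fixed"))
  # the never-flipping residue legitimately warns about its short window
  sims <- suppressWarnings(
    lapply(models, sample_dwell_process, total_ns = 300, dt_ps = 10))
  series <- lapply(sims, function(s) synth_chi_series(s$states))
  rep_df <- dwell_report(series)
  expect_equal(rep_df$n_transitions,
               vapply(sims, function(s) s$ledger$n_transitions, numeric(1)),
               ignore_attr = TRUE)
  # the never-flipping residue prints the dash convention
  fmt <- format_dwell_report(rep_df)
  expect_equal(fmt[2, "7"], "–")
  expect_match(fmt[1, "7"], "^0/")

  # debouncing can only remove transitions
  rep0 <- dwell_report(series, min_dwell = 0)
  expect_true(all(rep_df$n_transitions <= rep0$n_transitions))
})

test_that("lifetime estimates and populations are recovered for an
           exponential alternating-renewal process", {
  sim <- sample_dwell_process(dwell_model(2, 8), total_ns = 5000, dt_ps = 10,
                              seed = 71)
  chi <- synth_chi_series(sim$states, seed = 72)
  st <- transition_stats(debounce_states(classify_conformer(chi), 300))
  # dwells are floored at the 300 ps debounce threshold, so the expected
  # means are 2.3 and 8.3 ns (memorylessness) and the stationary syn
  # fraction is 2.3/10.6
  expect_lt(abs(st$mean_lifetime_syn_ns - 2.3) / 2.3, 0.1)
  expect_lt(abs(st$mean_lifetime_anti_ns - 8.3) / 8.3, 0.1)
  expect_lt(abs(st$syn_population - 2.3 / 10.6), 0.02)
  # and the estimates track the ledger's realised draws even more closely
  expect_lt(abs(st$mean_lifetime_syn_ns - sim$ledger$mean_dwell_syn_ns) /
              sim$ledger$mean_dwell_syn_ns, 0.1)
})
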