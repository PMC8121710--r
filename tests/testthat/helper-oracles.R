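# Independent oracles and in-code fixtures shared across the test files.

# Brute-force debounce oracle: sequential left-to-right scan over the raw
# runs, merging every excursion shorter than min_dwell into the currently
# accepted state; the initial run is always accepted and the final run is
# accepted regardless of length.  Deliberately a plain loop, independent of
# the package's vectorised anchor formulation.
debounce_oracle <- function(labels, dt, min_dwell) {
  n <- length(labels)
  bounds <- c(0L, which(labels[-1L] != labels[-n]), n)
  out <- labels
  cur <- labels[1L]
  nrun <- length(bounds) - 1L
  for (k in seq_len(nrun)) {
    from <- bounds[k] + 1L
    to <- bounds[k + 1L]
    s <- labels[from]
    if (s != cur) {
      if (k == nrun || (to - from + 1L) * dt >= min_dwell) cur <- s
    }
    out[from:to] <- cur
  }
  out
}

# Random two-state label sequences; `persist` controls run lengths
# (probability of staying in the current state each frame).
random_labels <- function(n, persist = 0.5) {
  flips <- stats::runif(n - 1) > persist
  states <- c("anti", "syn")
  idx <- 1L + (cumsum(c(stats::rbinom(1, 1, 0.5), flips)) %% 2L)
  states[idx]
}

# Independent run scanner for occupancy checks.
run_stats_oracle <- function(present, dt) {
  n <- length(present)
  events <- 0L
  lengths <- integer(0)
  i <- 1L
  while (i <= n) {
    if (present[i]) {
      j <- i
      while (j <= n && present[j]) j <- j + 1L
      events <- events + 1L
      lengths <- c(lengths, j - i)
      i <- j
    } else i <- i + 1L
  }
  list(fraction = sum(present) / n, events = events,
       mean_lifetime_ps = if (events > 0) mean(lengths) * dt else NA_real_)
}

# Small two-residue RNA-like fixture written as PDB text, entirely in code.
# 40 atoms: residue 13 (A, chain R) with a full purine nucleotide's worth of
# atoms, residue 14 (U, chain B) with pyrimidine atoms.
write_two_residue_pdb <- function(path) {
  a_names <- c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "O4'", "C3'", "O3'",
               "C2'", "O2'", "C1'", "N9", "C8", "N7", "C5", "C6", "N6",
               "N1", "C2", "N3", "C4")
  u_names <- c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "O4'", "C3'", "O3'",
               "C2'", "O2'", "C1'", "N1", "C2", "O2", "N3", "C4", "O4")
  set.seed(99)
  fmt <- function(i, nm, res, ch, rn, xyz) {
    sprintf("ATOM  %5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            i, nm, res, ch, rn, xyz[1], xyz[2], xyz[3],
            substr(gsub("'", "", nm), 1, 1))
  }
  lines <- character(0)
  i <- 0
  for (nm in a_names) {
    i <- i + 1
    lines <- c(lines, fmt(i, nm, "A", "R", 13, stats::runif(3, 0, 20)))
  }
  for (nm in u_names) {
    i <- i + 1
    lines <- c(lines, fmt(i, nm, "U", "B", 14, stats::runif(3, 0, 20)))
  }
  writeLines(c(lines, "END"), path)
  list(n_atoms = length(a_names) + length(u_names), n_res = 2L)
}

# Trajectory from raw coordinates and minimal atom metadata, for geometric
# detector tests.  `coords` is n_frames x n_atoms x 3.
toy_trajectory <- function(coords, names, elements, dt = 10,
                           resno = seq_along(names), chain = "X",
                           resname = "UNK") {
  top <- topology(data.frame(
    name = names, element = elements,
    chain = rep_len(chain, length(names)),
    resno = rep_len(resno, length(names)),
    resname = rep_len(resname, length(names)), stringsAsFactors = FALSE))
  trajectory(top, coords, dt = dt)
}

# Random rigid transform applied to every atom of every frame.
apply_random_rigid <- function(traj) {
  th <- stats::runif(3, 0, 2 * pi)
  Rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])),
              c(0, sin(th[1]), cos(th[1])))
  Ry <- rbind(c(cos(th[2]), 0, sin(th[2])), c(0, 1, 0),
              c(-sin(th[2]), 0, cos(th[2])))
  Rz <- rbind(c(cos(th[3]), -sin(th[3]), 0),
              c(sin(th[3]), cos(th[3]), 0), c(0, 0, 1))
  R <- Rx %*% Ry %*% Rz
  shift <- stats::runif(3, -50, 50)
  out <- traj
  for (f in seq_len(n_frames(traj))) {
    x <- traj$coords[f, , , drop = TRUE]
    dim(x) <- c(dim(traj$coords)[2], 3)
    out$coords[f, , ] <- sweep(x %*% t(R), 2, shift, `+`)
  }
  out
}
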