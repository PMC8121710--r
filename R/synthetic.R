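# Ground-truth-labelled synthetic data.
#
# The generator emulates the statistical structure the analysis assumes --
# per-nucleotide alternating syn/anti dwells on nanosecond timescales,
# sub-threshold excursions ("blips") on the 100-200 ps scale, chi wells
# inside the classification windows, and schedulable interface geometries --
# and emits a ledger that exactly describes every emitted frame, so pipeline
# output can be compared against known truth.  It mimics statistics, not
# physics: frames are independent snapshots with no dynamics or solvent.

#' Alternating-renewal dwell model
#'
#' Describes one nucleotide's syn/anti flip process: alternating dwells with
#' the given means, optionally decorated with short-lived excursions to the
#' opposite state ("blips") that a 300 ps debounce should remove.
#'
#' Dwell durations are drawn above `dwell_floor_ps`: a true dwell shorter
#' than the debounce threshold is observationally indistinguishable from a
#' blip, so sub-threshold excursions are represented only through the
#' explicit blip channel.  For exponential dwells the realised mean is
#' therefore `mean + floor` (memorylessness of the exponential), which the
#' ledger records.
#'
#' @param mean_syn_ns,mean_anti_ns mean dwell of each state, ns (> 0).
#' @param distribution `"exponential"` (default) or `"fixed"` (every dwell
#'   exactly at its mean, for exact-count tests).
#' @param blip_rate_per_ns expected number of blips per ns of dwell
#'   (default 0: none).
#' @param blip_duration_ps duration of each blip, ps; must stay below 300 ps
#'   when blips are enabled.
#' @param initial starting state, `"anti"` (default) or `"syn"`.
#' @param dwell_floor_ps lower bound on true dwell durations, ps
#'   (default 300, the debounce threshold; 0 disables the floor).
#' @return A `DwellModel` list.
#' @export
dwell_model <- function(mean_syn_ns, mean_anti_ns,
                        distribution = c("exponential", "fixed"),
                        blip_rate_per_ns = 0, blip_duration_ps = 150,
                        initial = c("anti", "syn"), dwell_floor_ps = 300) {
  distribution <- match.arg(distribution)
  initial <- match.arg(initial)
  stopifnot(mean_syn_ns > 0, mean_anti_ns > 0, blip_rate_per_ns >= 0,
            dwell_floor_ps >= 0)
  if (blip_rate_per_ns > 0 && blip_duration_ps >= 300)
    stop("blip duration must be < 300 ps (otherwise it is a real dwell)")
  structure(list(mean_syn_ns = mean_syn_ns, mean_anti_ns = mean_anti_ns,
                 distribution = distribution,
                 blip_rate_per_ns = blip_rate_per_ns,
                 blip_duration_ps = blip_duration_ps,
                 initial = initial, dwell_floor_ps = dwell_floor_ps),
            class = "DwellModel")
}

.draw_dwell <- function(model, state) {
  mean_ps <- 1000 * if (state == "syn") model$mean_syn_ns else
    model$mean_anti_ns
  if (model$distribution == "fixed") return(max(mean_ps, model$dwell_floor_ps))
  repeat {
    d <- stats::rexp(1, rate = 1 / mean_ps)
    if (d >= model$dwell_floor_ps) return(d)
  }
}

#' Sample a labelled syn/anti state series with ground truth
#'
#' Simulates the alternating-renewal process of [dwell_model()] over a fixed
#' observation window, samples it on the frame grid, inserts scheduled
#' blips, and returns both the frame labels and a ledger listing every true
#' dwell and blip.
#'
#' @param model a [dwell_model()].
#' @param total_ns observation window, ns.
#' @param dt_ps frame interval, ps; must not exceed the blip duration when
#'   blips are enabled (they would be unrepresentable).
#' @param seed optional RNG seed for reproducibility.
#' @return List with `states` (a `StateSeries` of raw labels) and `ledger`:
#'   dwell table (state, start/end ps, censored flag), blip table,
#'   `n_transitions` (between true dwells), `n_blips`, the continuous-time
#'   `syn_fraction`, and realised mean dwells per state over completed
#'   dwells.
#' @export
sample_dwell_process <- function(model, total_ns, dt_ps, seed = NULL) {
  stopifnot(inherits(model, "DwellModel"), total_ns > 0, dt_ps > 0)
  if (model$blip_rate_per_ns > 0 && dt_ps > model$blip_duration_ps)
    stop("dt (", dt_ps, " ps) exceeds the blip duration (",
         model$blip_duration_ps, " ps); blips would be unrepresentable")
  if (total_ns < 3 * (model$mean_syn_ns + model$mean_anti_ns))
    warning("observation window is short relative to the mean dwells; ",
            "statistics will be noisy")
  if (!is.null(seed)) set.seed(seed)
  n <- round(total_ns * 1000 / dt_ps)
  total_ps <- n * dt_ps
  t_last <- (n - 1) * dt_ps

  state <- model$initial
  starts <- numeric(0); states <- character(0)
  cum <- 0
  while (cum < total_ps) {
    starts <- c(starts, cum); states <- c(states, state)
    cum <- cum + .draw_dwell(model, state)
    state <- if (state == "syn") "anti" else "syn"
  }
  # a dwell that starts after the last frame time owns no frame: fold it
  # into its predecessor
  keep <- starts <= t_last
  starts <- starts[keep]; states <- states[keep]
  ends <- c(starts[-1L], total_ps)
  nd <- length(starts)
  dwells <- data.frame(state = states, start_ps = starts, end_ps = ends,
                       duration_ps = ends - starts,
                       censored = c(rep(FALSE, nd - 1L), TRUE),
                       stringsAsFactors = FALSE)

  tgrid <- (seq_len(n) - 1L) * dt_ps
  labels <- states[findInterval(tgrid, starts)]

  # blips: interior, mutually separated excursions inside completed dwells,
  # kept clear of the dwell edges so debouncing sees full-length context
  blips <- data.frame(start_ps = numeric(0), duration_ps = numeric(0),
                      from_state = character(0), stringsAsFactors = FALSE)
  if (model$blip_rate_per_ns > 0) {
    dur <- model$blip_duration_ps
    margin <- max(300, 2 * dt_ps)
    for (i in seq_len(nd)) {
      lo <- dwells$start_ps[i] + margin
      hi <- dwells$end_ps[i] - margin - dur
      if (hi <= lo) next
      k <- stats::rpois(1, model$blip_rate_per_ns * dwells$duration_ps[i] /
                          1000)
      if (k == 0L) next
      cand <- sort(stats::runif(k, lo, hi))
      kept <- numeric(0)
      for (b in cand)
        if (length(kept) == 0L || b >= kept[length(kept)] + dur + margin)
          kept <- c(kept, b)
      if (length(kept) > 0L)
        blips <- rbind(blips, data.frame(
          start_ps = kept, duration_ps = dur,
          from_state = dwells$state[i], stringsAsFactors = FALSE))
    }
    for (j in seq_len(nrow(blips))) {
      hit <- tgrid >= blips$start_ps[j] &
        tgrid < blips$start_ps[j] + blips$duration_ps[j]
      labels[hit] <- if (blips$from_state[j] == "syn") "anti" else "syn"
    }
  }

  syn_time <- sum(dwells$duration_ps[dwells$state == "syn"])
  if (nrow(blips) > 0L) {
    syn_time <- syn_time -
      sum(blips$duration_ps[blips$from_state == "syn"]) +
      sum(blips$duration_ps[blips$from_state == "anti"])
  }
  completed <- !dwells$censored
  mean_completed <- function(s) {
    d <- dwells$duration_ps[completed & dwells$state == s]
    if (length(d) == 0L) NA_real_ else mean(d) / 1000
  }
  ledger <- list(
    dwells = dwells, blips = blips,
    n_transitions = nd - 1L, n_blips = nrow(blips),
    syn_fraction = syn_time / total_ps,
    mean_dwell_syn_ns = mean_completed("syn"),
    mean_dwell_anti_ns = mean_completed("anti"),
    model = unclass(model), total_ns = total_ns, dt_ps = dt_ps)
  list(states = state_series(labels, dt_ps), ledger = ledger)
}

#' Chi well model
#'
#' Gaussian wells (wrapped on the circle) for the syn and anti conformers.
#' Defaults centre the wells at 60 and 240 degrees, well inside the
#' classification windows.
#'
#' @param mean_syn,mean_anti well centres, degrees.
#' @param sd circular standard deviation, degrees.
#' @param windows the classification windows the wells must respect.
#' @export
chi_well_model <- function(mean_syn = 60, mean_anti = 240, sd = 15,
                           windows = state_windows()) {
  stopifnot(sd > 0)
  lab <- function(x) {
    offset <- (x - windows$syn_lo) %% 360
    if (offset < windows$width) "syn" else "anti"
  }
  if (lab(mean_syn) != "syn" || lab(mean_anti) != "anti")
    stop("well means must lie inside their classification windows")
  edge_dist <- function(x) {
    offs <- abs(((x - c(windows$syn_lo, windows$syn_hi) + 180) %% 360) - 180)
    min(offs)
  }
  if (edge_dist(mean_syn) < 2 * sd || edge_dist(mean_anti) < 2 * sd)
    warning("a well mean lies within 2 sd of a window boundary; ",
            "label recovery will degrade")
  structure(list(mean_syn = mean_syn, mean_anti = mean_anti, sd = sd),
            class = "ChiWellModel")
}

#' Synthesise a chi series from state labels
#'
#' Draws each frame's chi from the wrapped Gaussian well of its state.  At
#' the default well width, re-classifying the output recovers the input
#' labels for essentially all frames (window edges are ~6 sd away).
#'
#' @param states a `StateSeries`.
#' @param wells a [chi_well_model()].
#' @param seed optional RNG seed.
#' @return An `AngleSeries` with the states' dt.
#' @export
synth_chi_series <- function(states, wells = chi_well_model(), seed = NULL) {
  stopifnot(inherits(states, "StateSeries"), inherits(wells, "ChiWellModel"))
  if (!is.null(seed)) set.seed(seed)
  mu <- ifelse(states$labels == "syn", wells$mean_syn, wells$mean_anti)
  angle_series(mu + stats::rnorm(length(mu), 0, wells$sd), states$dt,
               residue = states$residue)
}
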