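# Two-state (syn/anti) classification, debouncing, and dwell statistics.
#
# The classification windows and the 300 ps debounce threshold are the
# package defaults for adenine glycosidic dynamics: a nucleotide is syn for
# chi in [-30, 150) deg and anti for chi in [150, 330) deg, and excursions to
# the opposite state shorter than the threshold are not counted as
# transitions.

#' Syn/anti classification windows
#'
#' The two windows partition the circle: every angle receives exactly one
#' label.  Windows are half-open on their upper edge, so exactly 150 deg is
#' anti and exactly 330 deg (= -30 deg) is syn.
#'
#' @param syn_lo,syn_hi boundaries of the syn window in degrees (defaults
#'   -30 and 150); the anti window is the complement.
#' @return A `StateWindows` object.
#' @export
state_windows <- function(syn_lo = -30, syn_hi = 150) {
  width <- (syn_hi - syn_lo) %% 360
  if (width == 0) stop("syn window must have nonzero width")
  structure(list(syn_lo = syn_lo %% 360, width = width,
                 syn_hi = syn_hi %% 360), class = "StateWindows")
}

#' Classify frames as syn or anti
#'
#' @param series an `AngleSeries` from [compute_chi()] or [angle_series()].
#' @param windows a [state_windows()] object.
#' @return A `StateSeries`: list with `labels` (character, "syn"/"anti"),
#'   `dt` (ps), `debounced = FALSE`, and the source residue label.
#' @export
classify_conformer <- function(series, windows = state_windows()) {
  stopifnot(inherits(series, "AngleSeries"), inherits(windows, "StateWindows"))
  offset <- (series$values - windows$syn_lo) %% 360
  labels <- ifelse(offset < windows$width, "syn", "anti")
  structure(list(labels = labels, dt = series$dt, debounced = FALSE,
                 min_dwell = 0, residue = series$residue),
            class = "StateSeries")
}

#' Build a StateSeries from labels
#' @param labels character vector over `{"syn", "anti"}` (or any two labels).
#' @param dt frame interval, ps.
#' @param debounced whether the series has already been debounced.
#' @param min_dwell debounce threshold used, ps.
#' @export
state_series <- function(labels, dt, debounced = FALSE, min_dwell = 0) {
  stopifnot(length(labels) > 0L, dt > 0)
  structure(list(labels = as.character(labels), dt = dt,
                 debounced = debounced, min_dwell = min_dwell,
                 residue = NA_character_),
            class = "StateSeries")
}

#' Remove short-lived state excursions
#'
#' Left-to-right hysteresis: scanning from the first frame, an excursion to
#' the opposite state is accepted as a real transition only if it persists
#' for at least `min_dwell` ps (run length times dt); shorter excursions are
#' relabelled to the currently accepted state.  The initial run is always
#' accepted, and the final run is accepted regardless of its length because
#' its true duration is censored by the end of the observation window.
#'
#' @param states a `StateSeries` (raw labels).
#' @param min_dwell minimum dwell in ps (default 300); 0 returns the input
#'   labels unchanged.
#' @return A debounced `StateSeries`.
#' @export
debounce_states <- function(states, min_dwell = 300) {
  stopifnot(inherits(states, "StateSeries"))
  if (min_dwell < 0) stop("min_dwell must be >= 0 ps")
  r <- rle(states$labels)
  vals <- r$values
  lens <- r$lengths
  nrun <- length(vals)
  if (nrun > 1L) {
    # Raw runs strictly alternate between the two states, so the scan
    # reduces to: a run is an "anchor" if it is long enough to be accepted
    # (or is the initial or the final, censored, run), and every run takes
    # the state of the last anchor at or before it.
    anchor <- lens * states$dt >= min_dwell
    anchor[c(1L, nrun)] <- TRUE
    aidx <- which(anchor)
    vals <- vals[aidx[findInterval(seq_len(nrun), aidx)]]
  }
  out <- states
  out$labels <- inverse.rle(list(values = vals, lengths = lens))
  out$debounced <- TRUE
  out$min_dwell <- min_dwell
  out
}

#' Dwell statistics of a debounced state series
#'
#' @param states a `StateSeries`, normally debounced.
#' @return A `DwellStats` list:
#'   \describe{
#'     \item{n_transitions}{number of label changes.}
#'     \item{syn_population}{fraction of frames labelled syn.}
#'     \item{time_to_first_ns}{simulation time at which the first transition
#'       occurred (ns); `NA` when no transition occurred.}
#'     \item{mean_lifetime_syn_ns, mean_lifetime_anti_ns}{average dwell of
#'       each state over completed runs only (runs terminated by a
#'       transition); `NA` when a state has no completed run.  The final,
#'       censored run contributes to the population but not to the
#'       lifetime means; means including it are reported separately.}
#'     \item{n_completed_syn, n_completed_anti}{completed-run counts.}
#'   }
#' @export
transition_stats <- function(states) {
  stopifnot(inherits(states, "StateSeries"))
  labels <- states$labels
  if (length(labels) == 0L) stop("empty state series")
  dt_ns <- states$dt / 1000
  r <- rle(labels)
  nrun <- length(r$values)
  n_trans <- nrun - 1L
  completed <- if (nrun > 1L) seq_len(nrun - 1L) else integer(0)
  mean_life <- function(state, runs) {
    sel <- runs[r$values[runs] == state]
    if (length(sel) == 0L) NA_real_ else mean(r$lengths[sel]) * dt_ns
  }
  list(
    n_transitions = n_trans,
    syn_population = mean(labels == "syn"),
    time_to_first_ns = if (n_trans > 0L) r$lengths[1] * dt_ns else NA_real_,
    mean_lifetime_syn_ns = mean_life("syn", completed),
    mean_lifetime_anti_ns = mean_life("anti", completed),
    mean_lifetime_syn_censored_ns = mean_life("syn", seq_len(nrun)),
    mean_lifetime_anti_censored_ns = mean_life("anti", seq_len(nrun)),
    n_completed_syn = sum(r$values[completed] == "syn"),
    n_completed_anti = sum(r$values[completed] == "anti"),
    censored_state = r$values[nrun],
    censored_length_ns = r$lengths[nrun] * dt_ns)
}

#' Per-residue dwell-statistic report
#'
#' Runs chi computation (when given a trajectory), classification,
#' debouncing and [transition_stats()] for a set of nucleotides and tabulates
#' the results: transitions and syn population, time until first transition,
#' and mean syn/anti lifetimes.
#'
#' @param x a [trajectory()] object, or a named list of `AngleSeries`.
#' @param residues residue numbers of the nucleotides (trajectory input
#'   only).
#' @param windows classification windows, see [state_windows()].
#' @param min_dwell debounce threshold in ps.
#' @param chain optional chain id (trajectory input only).
#' @return A data.frame with one row per residue and the [transition_stats()]
#'   columns; the classic three-row presentation is produced by
#'   [format_dwell_report()].
#' @export
dwell_report <- function(x, residues = NULL, windows = state_windows(),
                         min_dwell = 300, chain = NULL) {
  series <- if (inherits(x, "Trajectory")) {
    stopifnot(!is.null(residues))
    setNames(lapply(residues, function(r) compute_chi(x, r, chain = chain)),
             as.character(residues))
  } else {
    stopifnot(is.list(x), all(vapply(x, inherits, logical(1), "AngleSeries")))
    x
  }
  rows <- lapply(names(series), function(nm) {
    st <- transition_stats(debounce_states(
      classify_conformer(series[[nm]], windows), min_dwell))
    data.frame(residue = nm,
               n_transitions = st$n_transitions,
               syn_population = st$syn_population,
               time_to_first_ns = st$time_to_first_ns,
               mean_lifetime_syn_ns = st$mean_lifetime_syn_ns,
               mean_lifetime_anti_ns = st$mean_lifetime_anti_ns,
               n_completed_syn = st$n_completed_syn,
               n_completed_anti = st$n_completed_anti,
               censored_state = st$censored_state,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "min_dwell") <- min_dwell
  out
}

.fmt_num <- function(x, digits = 0) {
  ifelse(is.na(x), "–", formatC(x, format = "f", digits = digits))
}

#' Format a dwell report in the three-row presentation
#'
#' Row I: "transitions/syn-population"; row II: time until first transition
#' (ns); row III: "mean syn lifetime/mean anti lifetime" (ns).  Absent values
#' (no transition, or no completed run of a state) print as an en dash.
#'
#' @param report output of [dwell_report()].
#' @return A character matrix with rows I/II/III and one column per residue.
#' @export
format_dwell_report <- function(report) {
  row1 <- paste0(report$n_transitions, "/",
                 formatC(report$syn_population, format = "f", digits = 2))
  row2 <- .fmt_num(report$time_to_first_ns)
  row3 <- ifelse(
    is.na(report$mean_lifetime_syn_ns) & is.na(report$mean_lifetime_anti_ns),
    "–",
    paste0(.fmt_num(report$mean_lifetime_syn_ns), "/",
           .fmt_num(report$mean_lifetime_anti_ns)))
  m <- rbind(row1, row2, row3)
  dimnames(m) <- list(
    c("I: transitions/syn population", "II: time to first transition (ns)",
      "III: mean lifetimes syn/anti (ns)"),
    report$residue)
  m
}

#' Per-frame chi/state trace
#'
#' Frame-by-frame table (time, chi, raw label, debounced label) for timeline
#' plots of flip dynamics.
#'
#' @param series an `AngleSeries`.
#' @inheritParams dwell_report
#' @return data.frame with columns frame, time_ps, chi, raw, debounced.
#' @export
state_trace <- function(series, windows = state_windows(), min_dwell = 300) {
  raw <- classify_conformer(series, windows)
  deb <- debounce_states(raw, min_dwell)
  data.frame(frame = seq_along(series$values),
             time_ps = (seq_along(series$values) - 1L) * series$dt,
             chi = series$values, raw = raw$labels, debounced = deb$labels,
             stringsAsFactors = FALSE)
}
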