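# Config-driven pipeline: validates a YAML/list config, runs the requested
# stages, writes TSV + JSON twins of every table, and records a manifest
# with checksums so a run is reproducible and auditable.

.default_config <- function() {
  list(
    seed = 1,
    dt_ps = 10,
    out_dir = "results",
    stages = c("simulate", "chi_states", "fingerprint", "histogram",
               "pca", "hbfix"),
    simulate = list(total_ns = 5000, n_frames_geom = 60),
    chi_states = list(residues = c(1, 4, 7, 10, 13, 16),
                      min_dwell_ps = 300,
                      syn_window = c(-30, 150)),
    fingerprint = list(hbond_dist_cutoff = 3.5, hbond_angle_cutoff = 120,
                       ion_cutoff = 3.5, vdw_cutoff = 4.5),
    histogram = list(bin_width = 0.1),
    pca = list(stride = 5, n_components = 10, selection = "backbone"),
    hbfix = list(eta = 1.0, r_full = 3.0, r_off = 4.0))
}

#' Reference configuration
#'
#' Every numeric default used by [run_pipeline()] in one place; the same
#' structure ships as `inst/extdata/reference_config.yaml`.
#'
#' @return Nested list of defaults.
#' @export
reference_config <- function() .default_config()

.merge_config <- function(user, defaults, path = "") {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0L)
    stop("unknown config key(s): ",
         paste0(path, unknown, collapse = ", "))
  out <- defaults
  for (k in names(user)) {
    out[[k]] <- if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]])))
      .merge_config(user[[k]], defaults[[k]], paste0(path, k, "."))
    else user[[k]]
  }
  out
}

#' Validate a run configuration
#'
#' Merges a user config (list, or path to a YAML file) over the package
#' defaults.  Unknown keys are errors, preventing silently ignored typos in
#' cutoffs.
#'
#' @param config list or YAML file path; `NULL` gives pure defaults.
#' @return The merged, validated config list.
#' @export
run_config <- function(config = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  cfg <- .merge_config(config, .default_config())
  stopifnot(cfg$dt_ps > 0, cfg$chi_states$min_dwell_ps >= 0,
            cfg$fingerprint$hbond_dist_cutoff > 0,
            cfg$pca$stride >= 1)
  bad <- setdiff(cfg$stages, .default_config()$stages)
  if (length(bad) > 0L)
    stop("unknown stage(s): ", paste(bad, collapse = ", "))
  cfg
}

.write_table <- function(df, out_dir, name, params = NULL) {
  tsv <- file.path(out_dir, paste0(name, ".tsv"))
  con <- file(tsv, "w")
  if (!is.null(params))
    writeLines(paste0("# ", name, ": ",
                      paste(names(params), unlist(params), sep = "=",
                            collapse = " ")), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  jsonlite::write_json(df, file.path(out_dir, paste0(name, ".json")),
                       auto_unbox = TRUE, digits = NA, na = "null")
  c(tsv, file.path(out_dir, paste0(name, ".json")))
}

#' Run the analysis pipeline
#'
#' Executes the configured stages in order on the synthetic fixture suite:
#' `simulate` (generate fixtures + ledger), `chi_states` (dwell report),
#' `fingerprint` (interaction occupancies on the geometry fixture),
#' `histogram` (state-conditioned K31(O)-O4' distance histograms), `pca`
#' (per-repeat nucleotide PCA) and `hbfix` (bias-energy profile of the
#' restrained pairs).  A manifest (JSON) records the package version, the
#' config, the seed and an md5 checksum of every output file.
#'
#' @param config see [run_config()].
#' @return The manifest, invisibly; written as `manifest.json` in the
#'   output directory.
#' @export
run_pipeline <- function(config = NULL) {
  cfg <- run_config(config)
  out_dir <- cfg$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  fixtures <- NULL
  fixture_dir <- file.path(out_dir, "fixtures")

  for (stage in cfg$stages) {
    if (stage == "simulate") {
      fixtures <- make_fixture_suite(
        fixture_dir, seed = cfg$seed, total_ns = cfg$simulate$total_ns,
        dt_ps = cfg$dt_ps, n_frames_geom = cfg$simulate$n_frames_geom)
      outputs <- c(outputs, unlist(fixtures$paths))
    }
    if (stage == "chi_states") {
      if (is.null(fixtures)) stop("stage 'chi_states' needs stage 'simulate'")
      chi <- utils::read.csv(fixtures$paths$dwell_chi, check.names = FALSE)
      series <- lapply(chi, angle_series, dt = cfg$dt_ps)
      win <- state_windows(cfg$chi_states$syn_window[1],
                           cfg$chi_states$syn_window[2])
      rep_df <- dwell_report(series, windows = win,
                             min_dwell = cfg$chi_states$min_dwell_ps)
      outputs <- c(outputs, .write_table(
        rep_df, out_dir, "dwell_report",
        params = list(min_dwell_ps = cfg$chi_states$min_dwell_ps,
                      dt_ps = cfg$dt_ps)))
    }
    if (stage %in% c("fingerprint", "histogram", "pca", "hbfix")) {
      if (is.null(fixtures)) stop("stage '", stage, "' needs stage 'simulate'")
      traj <- load_trajectory(fixtures$paths$geometry, dt = cfg$dt_ps)
      sched <- fixtures$geometry_schedule
      if (stage == "fingerprint") {
        fp <- cfg$fingerprint
        rows <- list()
        for (r in seq_along(sched$repeats)) {
          resno <- 3L * r - 2L
          top <- traj$topology
          hb <- detect_hbond(
            traj, donor = atom_index(top, 100 * r + 33, "N"),
            acceptor = atom_index(top, resno, "N7", chain = "R"),
            dist_cutoff = fp$hbond_dist_cutoff,
            angle_cutoff = fp$hbond_angle_cutoff,
            label = sprintf("Q33(N)-A%d(N7)", resno))
          wb <- detect_water_bridge(
            traj, atom_index(top, resno, "O2'", chain = "R"),
            atom_index(top, 50 + r, "O2'", chain = "R"),
            waters = atom_index(top, 500 + r, "O", chain = "W"),
            dist_cutoff = fp$hbond_dist_cutoff,
            label = sprintf("water bridge A%d-A_R", resno))
          ib <- detect_ion_bridge(
            traj, ions = atom_index(top, 900 + r, "K", chain = "I"),
            atom_index(top, 100 * r + 28, "O"),
            atom_index(top, 100 * r + 27, "O"),
            cutoff = fp$ion_cutoff,
            label = sprintf("K+ bridge N28/N27 site %d", r))
          for (s in list(hb, wb, ib)) {
            oc <- occupancy(s)
            rows[[length(rows) + 1L]] <- data.frame(
              interaction = oc$label, fraction = oc$fraction,
              events = oc$events, mean_lifetime_ps = oc$mean_lifetime_ps)
          }
        }
        for (s in seq_along(sched$n_pocket_engaged)) {
          nrep <- length(sched$repeats)
          vdw <- detect_vdw_contact(
            traj, select_atoms(traj$topology,
                               paste("chain R and resid", 70 + s)),
            select_atoms(traj$topology,
                         paste("chain P and resid", 100 * (nrep + s) + 30)),
            cutoff = fp$vdw_cutoff,
            label = sprintf("I30 vdW, N-pocket site %d", s))
          oc <- occupancy(vdw)
          rows[[length(rows) + 1L]] <- data.frame(
            interaction = oc$label, fraction = oc$fraction,
            events = oc$events, mean_lifetime_ps = oc$mean_lifetime_ps)
        }
        bph <- occupancy(detect_4bph(traj, 18, 3, chain = "R",
                                     target_chain = "R",
                                     label = "G18-A3 4BPh"))
        rows[[length(rows) + 1L]] <- data.frame(
          interaction = bph$label, fraction = bph$fraction,
          events = bph$events, mean_lifetime_ps = bph$mean_lifetime_ps)
        outputs <- c(outputs, .write_table(
          do.call(rbind, rows), out_dir, "occupancy",
          params = cfg$fingerprint))
      }
      if (stage == "histogram") {
        rows <- list()
        for (r in seq_along(sched$repeats)) {
          resno <- 3L * r - 2L
          d <- distance_series(traj,
                               atom_index(traj$topology, 100 * r + 31, "O"),
                               atom_index(traj$topology, resno, "O4'",
                                          chain = "R"))
          st <- state_series(sched$repeats[[r]]$states, cfg$dt_ps)
          h <- state_conditioned_histogram(d, st,
                                           bin_width = cfg$histogram$bin_width)
          mids <- utils::head(h$breaks, -1) + h$bin_width / 2
          for (s in names(h$masses))
            rows[[length(rows) + 1L]] <- data.frame(
              residue = resno, state = s, bin_mid = mids,
              mass = h$masses[[s]])
        }
        outputs <- c(outputs, .write_table(
          do.call(rbind, rows), out_dir, "k31_o4p_histogram",
          params = cfg$histogram))
      }
      if (stage == "pca") {
        sel <- select_atoms(traj$topology, "chain R and resid 1 and not hydrogen")
        fitted <- superpose(traj, sel)
        pc <- traj_pca(fitted, sel, stride = cfg$pca$stride,
                       n_components = cfg$pca$n_components)
        pca_df <- data.frame(
          component = seq_len(ncol(pc$vectors)),
          eigenvalue = pc$eigenvalues[seq_len(ncol(pc$vectors))],
          fraction = pc$eigenvalues[seq_len(ncol(pc$vectors))] /
            max(pc$trace, .Machine$double.eps))
        outputs <- c(outputs, .write_table(pca_df, out_dir, "pca_spectrum",
                                           params = cfg$pca))
      }
      if (stage == "hbfix") {
        par <- hbfix_params(cfg$hbfix$eta, cfg$hbfix$r_full, cfg$hbfix$r_off)
        top <- traj$topology
        pairs <- lapply(seq_along(sched$repeats), function(r)
          hbfix_pair(atom_index(top, 100 * r + 31, "N"),
                     atom_index(top, 3L * r - 2L, "OP2", chain = "R"),
                     par, label = sprintf("K31(N)-A%d(OP2)", 3 * r - 2)))
        be <- trajectory_bias_energy(traj, pairs)
        hb_df <- data.frame(frame = seq_along(be$per_frame),
                            bias_kcal_mol = be$per_frame)
        outputs <- c(outputs, .write_table(hb_df, out_dir, "hbfix_bias",
                                           params = cfg$hbfix))
      }
    }
  }

  manifest <- list(
    package = "nucleoflip",
    version = as.character(utils::packageVersion("nucleoflip")),
    seed = cfg$seed,
    config = cfg,
    config_md5 = digest_config(cfg),
    outputs = lapply(sort(unique(outputs)), function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# md5 of the canonical JSON serialisation of a config
digest_config <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}
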