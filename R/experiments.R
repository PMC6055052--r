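# Scripted end-to-end experiments: two-compartment, three-compartment,
# open-field, and the two circular-arena landmark experiments, each running
# environment construction, a learning walk, the frozen-weight test phase,
# and the full analysis pipeline.

#' Experiment configuration
#'
#' @param experiment one of `"two_comp"`, `"three_comp"`, `"open_field"`,
#'   `"landmark_distal"`, `"landmark_proximal"`.
#' @param duration learning duration, seconds (default 600).
#' @param test_duration frozen-weight test duration, seconds; defaults to 30
#'   (fixed-rotation protocol) or 120 for the landmark experiments (free walk
#'   with learning off).
#' @param seed integer seed controlling walk, weights, and noise.
#' @param network named list of [network_params()] overrides.
#' @param motion named list of [motion_params()] overrides.
#' @param out_dir optional directory for CSV/JSON output.
#' @param record_every learning-phase rate subsampling (steps).
#' @return list of class `experiment_config`.
#' @export
experiment_config <- function(experiment = c("two_comp", "three_comp",
                                             "open_field", "landmark_distal",
                                             "landmark_proximal"),
                              duration = 600, test_duration = NULL, seed = 1,
                              network = list(), motion = list(),
                              out_dir = NULL, record_every = 10) {
  if (length(experiment) != 1 || !experiment %in% c(
    "two_comp", "three_comp", "open_field", "landmark_distal",
    "landmark_proximal")) {
    stop("unknown experiment; valid names: two_comp, three_comp, open_field, ",
         "landmark_distal, landmark_proximal")
  }
  landmark <- grepl("^landmark", experiment)
  if (is.null(test_duration)) test_duration <- if (landmark) 120 else 30
  stopifnot(duration > 0, test_duration > 0)
  structure(list(experiment = experiment, duration = duration,
                 test_duration = test_duration, seed = as.integer(seed),
                 network = network, motion = motion, out_dir = out_dir,
                 record_every = record_every),
            class = "experiment_config")
}

# experiment-specific parameter defaults, overridable from the config
experiment_network_params <- function(config) {
  over <- switch(config$experiment,
    # the open field widens the visual pathway (sigma 40 up from 20); the
    # widened, unnormalised weight profile carries more total drive (folded
    # into g_vis_bd) and the bidirectional layer runs in the weak-competition
    # additive regime that the Gaussian-overlap capacity analysis assumes
    open_field = list(sigma_vis_bd = 40, sigma_input_vis = 40,
                      g_vis_bd = 2.4, k_bd = 0.1),
    landmark_distal = ,
    landmark_proximal = list(g_fb_rsc = 0.3),
    list())
  over[names(config$network)] <- config$network
  do.call(network_params, over)
}

#' Run one end-to-end experiment
#'
#' Builds the apparatus, simulates the learning walk (600 s by default),
#' appends the frozen-weight test phase (the fixed-rotation sampling
#' protocol, or a 120 s free walk for the landmark experiments), and runs
#' the analysis pipeline: per-cell tuning curves (whole apparatus and per
#' compartment), rotational autocorrelations with layer means, cell
#' classifications, weight-development correlations, and (landmark modes) an
#' ADN drift report.
#'
#' @param config an `experiment_config` (or arguments forwarded to
#'   [experiment_config()]).
#' @return an `experiment_report`: list with `config`, `record`, `curves`,
#'   `acorr` (per-layer mean autocorrelation, whole + per compartment),
#'   `classification`, `weight_corr`, and `drift`/`landmarks` for the
#'   landmark experiments.
#' @export
run_experiment <- function(config = experiment_config(), ...) {
  if (!inherits(config, "experiment_config")) {
    config <- experiment_config(config, ...)
  }
  p <- experiment_network_params(config)
  landmark <- grepl("^landmark", config$experiment)
  landmarks <- NULL
  if (landmark) {
    arena <- build_circular_arena(sub("landmark_", "", config$experiment))
    env <- arena$env
    landmarks <- arena$landmarks
  } else {
    env <- switch(config$experiment,
                  two_comp = build_two_compartment(),
                  three_comp = build_three_compartment(),
                  open_field = build_open_field())
  }
  mo <- config$motion
  mo$dt <- mo$dt %||% p$dt
  mo$duration <- config$duration + if (landmark) config$test_duration else 0
  mp <- do.call(motion_params, mo)

  walk <- random_walk(env, mp, seed = config$seed)
  path <- if (landmark) walk else
    concat_paths(walk, sampling_protocol(env, total = config$test_duration,
                                         dt = p$dt,
                                         start_time = config$duration))
  record <- run_simulation(env, path, p,
                           mode = if (landmark) "attractor" else "clamped",
                           plasticity_schedule = c(0, config$duration),
                           landmarks = landmarks, seed = config$seed,
                           record_every = config$record_every)
  report <- analyze_record(record, config)
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

# full tuning-curve / autocorrelation / classification analysis of a record
analyze_record <- function(record, config) {
  layers <- c("adn", "rsc", "conj", "env")
  curves <- list()
  acorr <- list()
  classification <- list()
  multi <- length(unique(record$path$compartment)) >= 2
  for (ly in layers) {
    sp <- split_by_compartment(record, ly)
    n_cells <- ncol(sp$whole$rates)
    whole <- lapply(seq_len(n_cells), function(i)
      make_tuning_curve(sp$whole$headings, sp$whole$rates[, i]))
    per_comp <- lapply(sp$comps, function(cc)
      lapply(seq_len(n_cells), function(i)
        make_tuning_curve(cc$headings, cc$rates[, i])))
    curves[[ly]] <- list(whole = whole, per_comp = per_comp)
    safe_ac <- function(cv) tryCatch(rotational_autocorrelation(cv),
                                     error = function(e) NULL)
    ac_whole <- Filter(Negate(is.null), lapply(whole, safe_ac))
    acorr[[ly]] <- list(
      whole = if (length(ac_whole)) mean_autocorr(ac_whole) else NULL,
      per_comp = lapply(per_comp, function(cl) {
        acs <- Filter(Negate(is.null), lapply(cl, safe_ac))
        if (length(acs)) mean_autocorr(acs) else NULL
      }))
    if (multi) {
      classification[[ly]] <- vapply(seq_len(n_cells), function(i)
        classify_cell(whole[[i]], lapply(per_comp, `[[`, i)), character(1))
    }
  }
  # development of the plastic weights toward their final state
  snaps <- record$snapshots
  combine <- function(s) list(
    hd_to_bd = cbind(s$rsc_conj, record$weights$rsc_env$values),
    bd_to_hd = rbind(s$conj_rsc, s$env_rsc))
  final <- combine(snaps$final)
  weight_corr <- do.call(rbind, lapply(c("Q1", "Q2", "Q3", "Q4", "final"),
    function(sn) {
      sc <- combine(snaps[[sn]])
      data.frame(snapshot = sn,
                 hd_to_bd = weight_profile_correlation(sc$hd_to_bd, final$hd_to_bd),
                 bd_to_hd = weight_profile_correlation(sc$bd_to_hd, final$bd_to_hd))
    }))
  report <- list(config = config, record = record, curves = curves,
                 acorr = acorr, classification = classification,
                 weight_corr = weight_corr)
  if (record$mode == "attractor") {
    report$drift <- drift_report(record)
  }
  structure(report, class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("<experiment_report: %s, seed %d>\n", x$config$experiment,
              x$config$seed))
  if (length(x$classification)) {
    for (ly in names(x$classification)) {
      tb <- table(x$classification[[ly]])
      cat(sprintf("  %s: %s\n", ly,
                  paste(names(tb), tb, sep = "=", collapse = ", ")))
    }
  }
  if (!is.null(x$drift)) {
    cat(sprintf("  ADN drift: mean %.2f deg, |mean| %.2f deg\n",
                x$drift$layer_mean, x$drift$layer_mean_abs))
  }
  invisible(x)
}

#' Per-quartile development of conjunctive-cell tuning
#'
#' Fraction of CONJ cells whose per-compartment tuning curves are "mature"
#' (at least bimodal for the two-compartment apparatus, trimodal for the
#' triangular one) in each learning quartile and in the test phase, per
#' compartment and for all compartments jointly.
#'
#' @param report an `experiment_report` from a multi-compartment experiment.
#' @param min_peaks maturity criterion; defaults to 3 for `three_comp`, else 2.
#' @return data.frame with columns `phase` (Q1-Q4, test), `compartment`
#'   (id or `"all"`), `proportion`.
#' @export
quartile_development <- function(report, min_peaks = NULL) {
  record <- report$record
  if (is.null(min_peaks)) {
    min_peaks <- if (record$env_kind == "three_comp") 3L else 2L
  }
  comp_ids <- sort(unique(record$path$compartment))
  if (length(comp_ids) < 2) stop("quartile development needs >= 2 compartments")
  n_cells <- ncol(record$learn$conj)
  t_learn <- record$path$time[record$learn$idx]
  comp_learn <- record$path$compartment[record$learn$idx]
  h_learn <- record$path$heading[record$learn$idx]
  t_stop <- record$schedule[2]

  mature_matrix <- function(sel) {
    # cells x compartments logical maturity from the selected learn samples
    vapply(comp_ids, function(id) {
      s <- sel & comp_learn == id
      if (sum(s) < 60) return(rep(FALSE, n_cells))
      vapply(seq_len(n_cells), function(i) {
        cv <- tryCatch(make_tuning_curve(h_learn[s], record$learn$conj[s, i]),
                       error = function(e) NULL)
        if (is.null(cv) || stats::sd(cv$rates) == 0) return(FALSE)
        count_peaks(rotational_autocorrelation(cv))$n_peaks >= min_peaks
      }, logical(1))
    }, logical(n_cells))
  }
  rows <- list()
  add_rows <- function(phase, mat) {
    for (k in seq_along(comp_ids)) {
      rows[[length(rows) + 1]] <<- data.frame(
        phase = phase, compartment = as.character(comp_ids[k]),
        proportion = mean(mat[, k]))
    }
    rows[[length(rows) + 1]] <<- data.frame(
      phase = phase, compartment = "all", proportion = mean(rowSums(mat) == ncol(mat)))
  }
  for (q in 1:4) {
    sel <- t_learn > (q - 1) / 4 * t_stop & t_learn <= q / 4 * t_stop
    add_rows(paste0("Q", q), mature_matrix(sel))
  }
  # test phase, from the analysed test curves
  test_mat <- vapply(seq_along(comp_ids), function(k) {
    vapply(seq_len(n_cells), function(i) {
      cv <- report$curves$conj$per_comp[[k]][[i]]
      if (stats::sd(cv$rates) == 0) return(FALSE)
      count_peaks(rotational_autocorrelation(cv))$n_peaks >= min_peaks
    }, logical(1))
  }, logical(n_cells))
  add_rows("test", test_mat)
  do.call(rbind, rows)
}

#' Compare distal and proximal landmark experiments
#'
#' Tabulates the ADN drift statistics of two landmark-experiment reports:
#' layer-mean signed deviation and mean absolute deviation, per mode, per
#' spatial quadrant, and per 30-s test window. Distal landmarks, whose
#' visibility is tightly tuned to head direction, should anchor the system
#' (smaller deviation) while proximal ones should not.
#'
#' @param distal_report,proximal_report `experiment_report`s from
#'   `landmark_distal` / `landmark_proximal` runs.
#' @return list with `summary`, `quadrants`, `windows` data frames and
#'   `seeds_matched`; a warning flags mismatched seeds.
#' @export
compare_landmark_modes <- function(distal_report, proximal_report) {
  reports <- list(distal = distal_report, proximal = proximal_report)
  if (any(vapply(reports, function(r) is.null(r$drift), TRUE))) {
    stop("both reports must come from landmark (attractor-mode) experiments")
  }
  matched <- distal_report$config$seed == proximal_report$config$seed
  if (!matched) warning("landmark reports use different seeds")
  summary <- do.call(rbind, lapply(names(reports), function(m) {
    d <- reports[[m]]$drift
    data.frame(mode = m, mean_dev = d$layer_mean, mean_abs_dev = d$layer_mean_abs)
  }))
  quadrants <- do.call(rbind, lapply(names(reports), function(m)
    cbind(mode = m, reports[[m]]$drift$quadrant_summary)))
  windows <- do.call(rbind, lapply(names(reports), function(m)
    cbind(mode = m, reports[[m]]$drift$window_summary)))
  list(summary = summary, quadrants = quadrants, windows = windows,
       seeds_matched = matched)
}

#' Write an experiment report to disk
#'
#' Tidy CSVs (tuning curves, classifications, weight correlations, drift)
#' plus a machine-readable JSON summary and the weight snapshots.
#'
#' @param report an `experiment_report`.
#' @param dir output directory (created if needed).
#' @return invisibly, `dir`.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rec <- report$record
  write_path_csv(structure(rec$path, class = c("agent_path", "data.frame"),
                           dt = rec$dt), file.path(dir, "path.csv"))
  # tidy tuning curves: layer, cell, scope, bin, rate
  rows <- lapply(names(report$curves), function(ly) {
    cl <- report$curves[[ly]]
    scopes <- c(list(whole = cl$whole), cl$per_comp)
    do.call(rbind, lapply(names(scopes), function(sc)
      do.call(rbind, lapply(seq_along(scopes[[sc]]), function(i) {
        cv <- scopes[[sc]][[i]]
        data.frame(layer = ly, cell = i, scope = sc,
                   bin_center = cv$bin_centers, rate = cv$rates)
      }))))
  })
  utils::write.csv(do.call(rbind, rows), file.path(dir, "tuning_curves.csv"),
                   row.names = FALSE)
  if (length(report$classification)) {
    cls <- do.call(rbind, lapply(names(report$classification), function(ly)
      data.frame(layer = ly,
                 cell = seq_along(report$classification[[ly]]),
                 class = report$classification[[ly]])))
    utils::write.csv(cls, file.path(dir, "classification.csv"), row.names = FALSE)
  }
  utils::write.csv(report$weight_corr, file.path(dir, "weight_correlation.csv"),
                   row.names = FALSE)
  if (!is.null(report$drift)) {
    utils::write.csv(report$drift$per_cell, file.path(dir, "drift_per_cell.csv"),
                     row.names = FALSE)
    utils::write.csv(report$drift$window_summary,
                     file.path(dir, "drift_windows.csv"), row.names = FALSE)
    utils::write.csv(report$drift$quadrant_summary,
                     file.path(dir, "drift_quadrants.csv"), row.names = FALSE)
  }
  write_snapshots_csv(rec, file.path(dir, "snapshots"))
  summary <- list(
    experiment = report$config$experiment, seed = report$config$seed,
    duration = report$config$duration,
    test_duration = report$config$test_duration,
    classification = lapply(report$classification,
                            function(cl) as.list(table(cl))),
    weight_corr_q1_hd_to_bd =
      report$weight_corr$hd_to_bd[report$weight_corr$snapshot == "Q1"],
    drift_mean = if (is.null(report$drift)) NULL else report$drift$layer_mean,
    drift_mean_abs = if (is.null(report$drift)) NULL else
      report$drift$layer_mean_abs)
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  yaml::write_yaml(unclass(report$config[c("experiment", "duration",
                                           "test_duration", "seed")]),
                   file.path(dir, "config.yaml"))
  invisible(dir)
}
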