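# End-to-end network simulation along an agent path. The loop is written
# against plain local matrices (rather than the `network_state` accessors)
# because it runs for tens of thousands of Euler steps; the layer equations
# are the same ones `rate_step()` / `adn_attractor_step()` implement.

#' Run a full network simulation along a path
#'
#' Drives the network with the agent's true heading and the locally visible
#' direction at every timestep of `path`, applying Hebbian learning inside
#' `plasticity_schedule` and freezing all weights outside it. In `clamped`
#' mode the ADN and VIS rings are Gaussian bumps centred on the true heading
#' and the compartment's visual direction; in `attractor` mode the ADN ring
#' integrates a noisy angular-velocity signal (drifting unless corrected
#' through the learned visual loop) and the VIS layer holds 12 binary
#' landmark detectors.
#'
#' @param env an `rsc_environment`.
#' @param path an `agent_path` covering learning and test phases.
#' @param params a `network_params`.
#' @param mode `"clamped"` or `"attractor"`.
#' @param plasticity_schedule `c(start, stop)` in seconds; weight snapshots
#'   are taken at the four quartiles of this window and at the end of the
#'   path.
#' @param landmarks `rsc_landmarks`, required in attractor mode.
#' @param seed seed for weight initialisation and path-integration noise.
#' @param record_every during the learning phase, store layer rates every
#'   this many steps (the test phase is always stored at full resolution).
#' @return a `simulation_record`: list with `path`, `test_idx`,
#'   `rates_test` (per-layer step x cell matrices over the test phase),
#'   `learn` (sub-sampled CONJ/ENV rates over the learning phase),
#'   `snapshots` (plastic-weight copies at Q1-Q4 and final), final
#'   `weights`, layer `pfds`, `params`, `mode`, `seed`.
#' @export
run_simulation <- function(env, path, params = network_params(),
                           mode = c("clamped", "attractor"),
                           plasticity_schedule = c(0, max(path$time)),
                           landmarks = NULL, seed = 1, record_every = 10) {
  mode <- match.arg(mode)
  p <- params
  n <- nrow(path)
  t_end <- path$time[n]
  sched <- plasticity_schedule
  if (length(sched) != 2 || sched[1] > sched[2] || sched[2] > t_end + 1e-9) {
    stop("plasticity_schedule must lie within the path duration")
  }
  if (mode == "attractor" && is.null(landmarks)) {
    stop("attractor mode requires a landmark array")
  }

  st <- network_state(p, mode = mode, seed = seed)
  pfds <- st$pfds
  W_ar <- st$weights$adn_rsc$values
  W_rc <- st$weights$rsc_conj$values
  W_cr <- st$weights$conj_rsc$values
  W_er <- st$weights$env_rsc$values
  W_vc <- st$weights$vis_conj$values
  W_ve <- st$weights$vis_env$values
  plast_rc <- st$weights$rsc_conj$plastic
  plast_fb <- st$weights$conj_rsc$plastic
  plast_vb <- st$weights$vis_conj$plastic   # TRUE only in attractor mode
  attract <- mode == "attractor"
  if (attract) {
    W_rec <- st$weights$adn_rec$values
    W_ra <- st$weights$rsc_adn$values
  }

  heading <- path$heading
  comp <- path$compartment
  # drive signals, precomputed in bulk
  if (!attract) {
    offs <- vapply(env$compartments, `[[`, numeric(1), "vis_offset")
    vis_dir <- wrap_angle(heading - offs[comp])
    D_adn <- gauss_drive(pfds$adn, heading, p$sigma_input)
    D_vis <- gauss_drive(pfds$vis, vis_dir, p$sigma_input_vis)
  } else {
    D_vis <- detector_drive(path, landmarks)
    omega <- c(0, angular_velocity_signal(path, p$noise_sd, seed = seed + 10))
    bin <- 360 / p$n_adn
  }

  dtt <- p$dt / p$tau
  lr <- p$learn_rate
  rmax <- p$rmax
  a_rsc <- st$act$rsc; a_conj <- st$act$conj; a_env <- st$act$env
  r_rsc <- st$rates$rsc; r_conj <- st$rates$conj; r_env <- st$rates$env
  if (attract) {
    st <- set_bump(st, heading[1])
    a_adn <- st$act$adn
    r_adn <- st$rates$adn
  }

  # recording layout
  test_idx <- which(path$time > sched[2] + 1e-9)
  n_test <- length(test_idx)
  test_from <- if (n_test) test_idx[1] else n + 1L
  R_test <- list(adn = matrix(0, n_test, p$n_adn),
                 rsc = matrix(0, n_test, p$n_rsc),
                 conj = matrix(0, n_test, p$n_conj),
                 env = matrix(0, n_test, p$n_env),
                 vis = matrix(0, n_test, nrow(W_vc)))
  learn_steps <- which(path$time <= sched[2] + 1e-9)
  sub_idx <- learn_steps[seq(1, length(learn_steps), by = record_every)]
  L_conj <- matrix(0, length(sub_idx), p$n_conj)
  L_env <- matrix(0, length(sub_idx), p$n_env)
  sub_ptr <- 1L

  snap_times <- sched[1] + (sched[2] - sched[1]) * (1:4) / 4
  snap_steps <- vapply(snap_times, function(tt) which.min(abs(path$time - tt)), 1L)
  snapshots <- vector("list", 5)
  names(snapshots) <- c("Q1", "Q2", "Q3", "Q4", "final")
  take_snapshot <- function() {
    s <- list(rsc_conj = W_rc, conj_rsc = W_cr, env_rsc = W_er)
    if (plast_vb) s[c("vis_conj", "vis_env")] <- list(W_vc, W_ve)
    s
  }

  for (t in seq_len(n)) {
    r_vis <- D_vis[, t]
    if (attract) {
      fb <- crossprod(W_ra, r_rsc)[, 1]
      inp <- crossprod(W_rec, r_adn)[, 1] + fb - p$k_adn * mean(r_adn)
      a_adn <- shift_ring(a_adn + dtt * (inp - a_adn), omega[t] * p$dt / bin)
      r_adn <- rmax * tanh(pmax(a_adn, 0) / rmax)
    } else {
      r_adn <- D_adn[, t]
    }
    inh_rsc <- p$k_rsc * mean(r_rsc)
    inh_conj <- p$k_bd * mean(r_conj)
    inh_env <- p$k_bd * mean(r_env)
    in_rsc <- crossprod(W_ar, r_adn)[, 1] +
      p$g_fb_rsc * (crossprod(W_cr, r_conj)[, 1] + crossprod(W_er, r_env)[, 1]) -
      inh_rsc
    in_conj <- crossprod(W_vc, r_vis)[, 1] +
      p$g_hd_conj * crossprod(W_rc, r_rsc)[, 1] - inh_conj
    in_env <- crossprod(W_ve, r_vis)[, 1] - inh_env
    a_rsc <- a_rsc + dtt * (in_rsc - a_rsc)
    a_conj <- a_conj + dtt * (in_conj - a_conj)
    a_env <- a_env + dtt * (in_env - a_env)
    r_rsc <- rmax * tanh(pmax(a_rsc, 0) / rmax)
    r_conj <- rmax * tanh(pmax(a_conj, 0) / rmax)
    r_env <- rmax * tanh(pmax(a_env, 0) / rmax)

    tt <- path$time[t]
    if (tt >= sched[1] && tt <= sched[2] + 1e-9) {
      if (plast_rc) {
        W_rc <- normalize_columns(W_rc + lr * tcrossprod(r_rsc, r_conj))
      }
      if (plast_fb) {
        W_cr <- normalize_columns(W_cr + lr * tcrossprod(r_conj, r_rsc))
        W_er <- normalize_columns(W_er + lr * tcrossprod(r_env, r_rsc))
      }
      if (plast_vb) {
        W_vc <- normalize_columns(W_vc + lr * tcrossprod(r_vis, r_conj))
        W_ve <- normalize_columns(W_ve + lr * tcrossprod(r_vis, r_env))
      }
    }

    if (t >= test_from) {
      ti <- t - test_from + 1L
      R_test$adn[ti, ] <- r_adn
      R_test$rsc[ti, ] <- r_rsc
      R_test$conj[ti, ] <- r_conj
      R_test$env[ti, ] <- r_env
      R_test$vis[ti, ] <- r_vis
    } else if (sub_ptr <= length(sub_idx) && t == sub_idx[sub_ptr]) {
      L_conj[sub_ptr, ] <- r_conj
      L_env[sub_ptr, ] <- r_env
      sub_ptr <- sub_ptr + 1L
    }
    k <- match(t, snap_steps)
    if (!is.na(k)) snapshots[[k]] <- take_snapshot()
  }
  snapshots$final <- take_snapshot()

  st$weights$rsc_conj$values <- W_rc
  st$weights$conj_rsc$values <- W_cr
  st$weights$env_rsc$values <- W_er
  st$weights$vis_conj$values <- W_vc
  st$weights$vis_env$values <- W_ve

  structure(list(
    env_kind = env$kind, env_center = env$center, mode = mode, params = p,
    seed = seed,
    path = as.data.frame(path), dt = attr(path, "dt"),
    schedule = sched, test_idx = test_idx,
    rates_test = R_test,
    learn = list(idx = sub_idx, conj = L_conj, env = L_env),
    snapshots = snapshots, snap_times = c(snap_times, t_end),
    weights = st$weights, pfds = pfds),
    class = "simulation_record")
}

#' @export
print.simulation_record <- function(x, ...) {
  cat(sprintf("<simulation_record: %s / %s, %d steps (%.0f s), test %d steps>\n",
              x$env_kind, x$mode, nrow(x$path), max(x$path$time),
              length(x$test_idx)))
  invisible(x)
}

# Gaussian bump drive for every timestep: cells x steps matrix
gauss_drive <- function(pfds, centers, sigma) {
  d <- outer(pfds, centers, circular_diff)
  exp(-d^2 / (2 * sigma^2))
}

# binary landmark-detector drive for every timestep: 12 x steps matrix
detector_drive <- function(path, landmarks, fov = 90) {
  out <- matrix(0, landmarks$count, nrow(path))
  for (i in seq_len(landmarks$count)) {
    dx <- landmarks$positions[i, 1] - path$x
    dy <- landmarks$positions[i, 2] - path$y
    bearing <- atan2(dx, dy) * 180 / pi
    out[i, ] <- as.numeric(abs(circular_diff(bearing, path$heading)) <= fov / 2)
  }
  out
}

#' Write weight snapshots to CSV
#'
#' One file per connection per snapshot, dense matrices with preferred
#' directions as row/column headers where available.
#'
#' @param record a `simulation_record`.
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
write_snapshots_csv <- function(record, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (snap in names(record$snapshots)) {
    for (conn in names(record$snapshots[[snap]])) {
      f <- file.path(dir, sprintf("weights_%s_%s.csv", conn, snap))
      utils::write.csv(record$snapshots[[snap]][[conn]], f, row.names = FALSE)
      files <- c(files, f)
    }
  }
  invisible(files)
}
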