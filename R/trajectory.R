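# Agent trajectories: random-walk exploration, the fixed-rotation sampling
# protocol used to build tuning curves, and noisy angular-velocity signals
# for path integration.
#
# An agent path is a data.frame of class "agent_path" with columns
# time, x, y, heading, compartment, teleport and attributes dt and seed.

#' Motion parameters for the random walk
#'
#' @param linear_speed constant forward speed, cm/s.
#' @param turn_sd heading noise, degrees per sqrt(second): the per-step
#'   Gaussian heading perturbation has sd `turn_sd * sqrt(dt)`.
#' @param dt integration step, seconds (shared with the network).
#' @param duration walk duration, seconds.
#' @param max_turn maximum goal-directed turning rate, degrees/s.
#' @param waypoint_tol distance (cm) at which a waypoint counts as reached.
#' @param waypoint_timeout give up on an unreached waypoint after this many
#'   seconds and draw a new one.
#' @return list of class `motion_params`.
#' @export
motion_params <- function(linear_speed = 20, turn_sd = 20, dt = 0.01,
                          duration = 600, max_turn = 180, waypoint_tol = 5,
                          waypoint_timeout = 20) {
  stopifnot(linear_speed > 0, turn_sd > 0, dt > 0, duration > 0, max_turn > 0)
  structure(list(linear_speed = linear_speed, turn_sd = turn_sd, dt = dt,
                 duration = duration, max_turn = max_turn,
                 waypoint_tol = waypoint_tol,
                 waypoint_timeout = waypoint_timeout),
            class = "motion_params")
}

# TRUE iff segment p->q crosses any wall segment (walls given as columns).
# Proper-intersection test via orientation signs; touching an endpoint counts
# as a crossing, which errs on the safe side for containment.
segment_blocked <- function(px, py, qx, qy, wx1, wy1, wx2, wy2) {
  if (length(wx1) == 0) return(FALSE)
  d1 <- (qx - px) * (wy1 - py) - (qy - py) * (wx1 - px)
  d2 <- (qx - px) * (wy2 - py) - (qy - py) * (wx2 - px)
  d3 <- (wx2 - wx1) * (py - wy1) - (wy2 - wy1) * (px - wx1)
  d4 <- (wx2 - wx1) * (qy - wy1) - (wy2 - wy1) * (qx - wx1)
  any(d1 * d2 <= 0 & d3 * d4 <= 0)
}

#' Random exploration path
#'
#' Random-waypoint walk: the agent draws a target uniformly over the
#' accessible interior, turns toward it (via the door when the straight line
#' is blocked by a partition) at a bounded turning rate with Gaussian heading
#' noise, and draws a new target on arrival. This covers all compartments and
#' headings and produces regular door transitions, which a pure
#' heading-diffusion walk essentially never achieves through a 10 cm door.
#' Moves that would cross a wall are rejected (the agent turns in place), so
#' every pose is inside the arena and compartment changes happen only through
#' doors. Fully reproducible from the seed.
#'
#' @param env an `rsc_environment`.
#' @param params a `motion_params` object.
#' @param seed integer RNG seed.
#' @param start optional start position (defaults to compartment 1's anchor).
#' @return an `agent_path` data.frame with `duration / dt` rows.
#' @export
#' @examples
#' env <- build_two_compartment()
#' path <- random_walk(env, motion_params(duration = 5), seed = 1)
#' nrow(path)  # 500
random_walk <- function(env, params = motion_params(), seed = 1, start = NULL) {
  if (length(env$compartments) == 0) stop("degenerate environment: no interior")
  n <- round(params$duration / params$dt)
  dt <- params$dt
  step_len <- params$linear_speed * dt
  max_turn <- params$max_turn * dt
  tol2 <- params$waypoint_tol^2
  timeout_steps <- round(params$waypoint_timeout / dt)
  wx1 <- env$walls[, "x1"]; wy1 <- env$walls[, "y1"]
  wx2 <- env$walls[, "x2"]; wy2 <- env$walls[, "y2"]
  circ <- env$kind == "circular"
  r2max <- if (circ) (env$radius - 1)^2 else Inf
  bb <- env$bbox
  door_center <- switch(env$kind, two_comp = c(80, 80), three_comp = c(0, 0),
                        NULL)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  draw_waypoint <- function() {
    repeat {
      p <- c(stats::runif(1, bb[1], bb[2]), stats::runif(1, bb[3], bb[4]))
      if (circ) { if (sum(p^2) <= r2max) return(p) }
      else if (in_environment(env, p)) return(p)
    }
  }

  x <- numeric(n); y <- numeric(n); h <- numeric(n)
  pos <- if (is.null(start)) env$compartments[[1]]$anchor else as.numeric(start)
  if (!in_environment(env, pos)) stop("start position outside environment")
  heading <- stats::runif(1, 0, 360)
  noise <- stats::rnorm(n, 0, params$turn_sd * sqrt(dt))
  wp <- draw_waypoint()
  wp_age <- 0L
  for (t in seq_len(n)) {
    if ((pos[1] - wp[1])^2 + (pos[2] - wp[2])^2 < tol2 || wp_age > timeout_steps) {
      wp <- draw_waypoint()
      wp_age <- 0L
    }
    wp_age <- wp_age + 1L
    goal <- wp
    if (!is.null(door_center) &&
        segment_blocked(pos[1], pos[2], wp[1], wp[2], wx1, wy1, wx2, wy2)) {
      goal <- door_center
    }
    desired <- atan2(goal[1] - pos[1], goal[2] - pos[2]) * 180 / pi
    turn <- circular_diff(desired, heading)
    heading <- (heading + max(-max_turn, min(max_turn, turn)) + noise[t]) %% 360
    rad <- heading * pi / 180
    qx <- pos[1] + step_len * sin(rad)
    qy <- pos[2] + step_len * cos(rad)
    ok <- if (circ) qx * qx + qy * qy <= r2max else
      (in_environment(env, c(qx, qy)) &&
         !segment_blocked(pos[1], pos[2], qx, qy, wx1, wy1, wx2, wy2))
    if (ok) {
      pos[1] <- qx; pos[2] <- qy
    }
    x[t] <- pos[1]; y[t] <- pos[2]; h[t] <- heading
  }
  comp <- path_compartments(env, x, y)
  path <- data.frame(time = seq_len(n) * dt, x = x, y = y, heading = h,
                     compartment = comp, teleport = FALSE)
  attr(path, "dt") <- dt
  attr(path, "seed") <- seed
  class(path) <- c("agent_path", "data.frame")
  path
}

# vectorised compartment lookup (positions assumed inside)
path_compartments <- function(env, x, y) {
  switch(env$kind,
    two_comp = ifelse(x <= 80, 1L, 2L),
    open_field = {
      east <- x >= 60; north <- y >= 60
      ifelse(east & north, 1L, ifelse(east, 2L, ifelse(!north, 3L, 4L)))
    },
    circular = rep(1L, length(x)),
    three_comp = {
      theta <- wrap_angle(atan2(x - env$center[1], y - env$center[2]) * 180 / pi)
      as.integer(floor(theta / 120) + 1L)
    })
}

#' Fixed-rotation sampling protocol
#'
#' Test-phase trajectory used to construct tuning curves free of sampling
#' bias: the agent rotates on the spot at a constant 36 degrees/s, teleporting
#' between a fixed point in each compartment so that total time is split
#' equally across compartments (15 s each in the two-compartment apparatus,
#' 10 s each in the three-compartment one). Every 6-degree heading bin is
#' visited in every compartment.
#'
#' @param env an `rsc_environment`.
#' @param total total protocol duration, seconds.
#' @param dt timestep, seconds.
#' @param start_time time of the first sample (protocol appended to a walk).
#' @param rotation_speed degrees per second.
#' @return an `agent_path`; `teleport` is `TRUE` on compartment changes.
#' @export
sampling_protocol <- function(env, total = 30, dt = 0.01, start_time = 0,
                              rotation_speed = 36) {
  ncomp <- length(env$compartments)
  if (ncomp < 1) stop("environment has no compartments")
  n <- round(total / dt)
  per <- n %/% ncomp
  idx <- rep(seq_len(ncomp), times = c(rep(per, ncomp - 1), n - per * (ncomp - 1)))
  anchors <- do.call(rbind, lapply(env$compartments, `[[`, "anchor"))
  tele <- c(FALSE, diff(idx) != 0)
  path <- data.frame(
    time = start_time + seq_len(n) * dt,
    x = anchors[idx, 1], y = anchors[idx, 2],
    heading = wrap_angle(rotation_speed * (seq_len(n) - 1) * dt),
    compartment = vapply(env$compartments, `[[`, integer(1), "id")[idx],
    teleport = tele)
  attr(path, "dt") <- dt
  attr(path, "seed") <- NA_integer_
  class(path) <- c("agent_path", "data.frame")
  path
}

#' Concatenate agent paths
#'
#' @param ... `agent_path` objects sharing a common `dt`, in time order.
#' @return a single `agent_path`.
#' @export
concat_paths <- function(...) {
  parts <- list(...)
  dt <- attr(parts[[1]], "dt")
  out <- do.call(rbind, lapply(parts, as.data.frame))
  attr(out, "dt") <- dt
  attr(out, "seed") <- attr(parts[[1]], "seed")
  class(out) <- c("agent_path", "data.frame")
  out
}

#' Noisy angular-velocity signal
#'
#' Per-step derivative of true heading plus zero-mean Gaussian noise, the
#' self-motion signal integrated by the head-direction attractor. With
#' `noise_sd = 0`, integrating the signal recovers the true heading exactly;
#' with noise the integrated heading performs a random walk around truth.
#'
#' @param path an `agent_path` with at least two poses.
#' @param noise_sd noise standard deviation, degrees/s.
#' @param seed integer RNG seed.
#' @return numeric vector of length `nrow(path) - 1`, degrees/s; entry `t`
#'   drives the transition from pose `t` to pose `t + 1`.
#' @export
angular_velocity_signal <- function(path, noise_sd = 0, seed = 1) {
  n <- nrow(path)
  if (n < 2) stop("path must contain at least two poses")
  dt <- attr(path, "dt")
  omega <- circular_diff(path$heading[-1], path$heading[-n]) / dt
  if (noise_sd > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    omega <- omega + stats::rnorm(n - 1, 0, noise_sd)
  }
  omega
}

#' Write an agent path to CSV
#'
#' @param path an `agent_path`.
#' @param file output file path.
#' @export
write_path_csv <- function(path, file) {
  utils::write.csv(as.data.frame(path), file, row.names = FALSE)
}

# Local RNG hygiene: simulations seed the global RNG but restore it afterwards
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) return(invisible())
  assign(".Random.seed", old, envir = globalenv())
}
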