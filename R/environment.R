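# Apparatus builders and visual-geometry queries.
#
# Coordinates are in cm; x = East, y = North. An environment is a list with
# class "rsc_environment":
#   name, kind          one of "two_comp", "three_comp", "open_field", "circular"
#   boundary            outer wall segments, matrix with columns x1,y1,x2,y2
#   walls               all impassable segments (boundary + partitions minus doors)
#   doors               gap segments agents may cross
#   compartments        list of: id, polygon (vertex matrix), vis_offset (deg),
#                       cue_card (segment or NULL), odor_label, anchor (point
#                       used by the fixed-rotation test protocol)
#   center, bbox        centre point and c(xmin, xmax, ymin, ymax)
#   radius              circular arenas only

seg <- function(x1, y1, x2, y2) c(x1 = x1, y1 = y1, x2 = x2, y2 = y2)

new_environment <- function(name, kind, boundary, walls, doors, compartments,
                            center, bbox, radius = NULL) {
  structure(
    list(name = name, kind = kind, boundary = boundary, walls = walls,
         doors = doors, compartments = compartments, center = center,
         bbox = bbox, radius = radius),
    class = "rsc_environment")
}

new_compartment <- function(id, polygon, vis_offset, cue_card = NULL,
                            odor_label = "", anchor) {
  list(id = id, polygon = polygon, vis_offset = wrap_angle(vis_offset),
       cue_card = cue_card, odor_label = odor_label, anchor = anchor)
}

#' @export
print.rsc_environment <- function(x, ...) {
  cat(sprintf("<rsc_environment '%s' (%s): %d compartment(s), %d wall segment(s)>\n",
              x$name, x$kind, length(x$compartments), nrow(x$walls)))
  for (cp in x$compartments) {
    cat(sprintf("  compartment %d: vis_offset %g deg %s\n", cp$id, cp$vis_offset,
                if (nzchar(cp$odor_label)) paste0("(", cp$odor_label, ")") else ""))
  }
  invisible(x)
}

#' Two-compartment apparatus
#'
#' A 160 x 160 cm box split by a central partition into two 160 x 80 cm
#' compartments connected by a single 10 cm door. The compartments are visual
#' 180-degree rotations of one another: cue cards sit on opposite outer walls
#' and the local visual direction in the second ("vanilla") compartment is
#' offset by 180 degrees from true heading.
#'
#' @return an `rsc_environment` with two compartments.
#' @export
#' @examples
#' env <- build_two_compartment()
#' vapply(env$compartments, `[[`, 0, "vis_offset")
build_two_compartment <- function() {
  W <- 160; P <- W / 2; door <- 10
  boundary <- rbind(seg(0, 0, W, 0), seg(W, 0, W, W), seg(W, W, 0, W), seg(0, W, 0, 0))
  partition <- rbind(seg(P, 0, P, (W - door) / 2), seg(P, (W + door) / 2, P, W))
  doors <- rbind(seg(P, (W - door) / 2, P, (W + door) / 2))
  comps <- list(
    new_compartment(1L, rbind(c(0, 0), c(P, 0), c(P, W), c(0, W)),
                    vis_offset = 0, cue_card = seg(0, 60, 0, 100),
                    odor_label = "lemon", anchor = c(P / 2, W / 2)),
    new_compartment(2L, rbind(c(P, 0), c(W, 0), c(W, W), c(P, W)),
                    vis_offset = 180, cue_card = seg(W, 100, W, 60),
                    odor_label = "vanilla", anchor = c(3 * P / 2, W / 2)))
  new_environment("two-compartment box", "two_comp", boundary,
                  rbind(boundary, partition), doors, comps,
                  center = c(P, W / 2), bbox = c(0, W, 0, W))
}

#' Three-compartment (triangular) apparatus
#'
#' Equilateral triangle with 120 cm walls, centred on the origin. A partition
#' runs from each corner toward the centroid, stopping 10 cm short of it, so
#' the three congruent compartments communicate through a central three-way
#' door. Local visual direction is aligned with true heading in compartment 1
#' and rotated by +120 / -120 degrees in the other two.
#'
#' @return an `rsc_environment` with three compartments.
#' @export
build_three_compartment <- function() {
  side <- 120; Rc <- side / sqrt(3); gap <- 10
  va <- c(0, 120, 240)                       # vertex compass angles
  vx <- Rc * heading_to_vec(va)              # vertices, rows
  px <- gap * heading_to_vec(va)             # inner partition endpoints
  nxt <- c(2, 3, 1)
  boundary <- do.call(rbind, lapply(1:3, function(k)
    seg(vx[k, 1], vx[k, 2], vx[nxt[k], 1], vx[nxt[k], 2])))
  partitions <- do.call(rbind, lapply(1:3, function(k)
    seg(vx[k, 1], vx[k, 2], px[k, 1], px[k, 2])))
  doors <- do.call(rbind, lapply(1:3, function(k)
    seg(px[k, 1], px[k, 2], px[nxt[k], 1], px[nxt[k], 2])))
  offs <- c(0, 120, 240)                     # 240 == -120
  comps <- lapply(1:3, function(k) {
    mid <- wrap_angle(va[k] + 60)            # bisector of the sector
    wall_dir <- (vx[nxt[k], ] - vx[k, ]); wall_dir <- wall_dir / sqrt(sum(wall_dir^2))
    mid_wall <- (vx[k, ] + vx[nxt[k], ]) / 2
    new_compartment(as.integer(k),
                    rbind(px[k, ], vx[k, ], vx[nxt[k], ], px[nxt[k], ]),
                    vis_offset = offs[k],
                    cue_card = seg(mid_wall[1] - 20 * wall_dir[1],
                                   mid_wall[2] - 20 * wall_dir[2],
                                   mid_wall[1] + 20 * wall_dir[1],
                                   mid_wall[2] + 20 * wall_dir[2]),
                    odor_label = c("lemon", "vanilla", "mint")[k],
                    anchor = 0.5 * Rc * heading_to_vec(mid)[1, ])
  })
  new_environment("three-compartment triangle", "three_comp", boundary,
                  rbind(boundary, partitions), doors, comps,
                  center = c(0, 0), bbox = c(-side / 2, side / 2, -Rc / 2, Rc))
}

#' Square open-field arena
#'
#' A 120 x 120 cm square with no internal walls. Its four quadrants act as
#' notional "compartments" whose local visual direction rotates by 90 degrees
#' between adjacent quadrants (offsets 0/90/180/270), modelling a network that
#' treats the four-fold symmetry of the box as four rotated compartments.
#'
#' @return an `rsc_environment` with four door-less quadrant compartments.
#' @export
build_open_field <- function() {
  W <- 120; h <- W / 2
  boundary <- rbind(seg(0, 0, W, 0), seg(W, 0, W, W), seg(W, W, 0, W), seg(0, W, 0, 0))
  quads <- list(  # NE, SE, SW, NW in clockwise order
    list(poly = rbind(c(h, h), c(W, h), c(W, W), c(h, W)), anchor = c(3 * h / 2, 3 * h / 2)),
    list(poly = rbind(c(h, 0), c(W, 0), c(W, h), c(h, h)), anchor = c(3 * h / 2, h / 2)),
    list(poly = rbind(c(0, 0), c(h, 0), c(h, h), c(0, h)), anchor = c(h / 2, h / 2)),
    list(poly = rbind(c(0, h), c(h, h), c(h, W), c(0, W)), anchor = c(h / 2, 3 * h / 2)))
  comps <- lapply(1:4, function(k)
    new_compartment(as.integer(k), quads[[k]]$poly, vis_offset = 90 * (k - 1),
                    anchor = quads[[k]]$anchor))
  new_environment("open field", "open_field", boundary, boundary,
                  doors = matrix(numeric(0), 0, 4,
                                 dimnames = list(NULL, c("x1", "y1", "x2", "y2"))),
                  comps, center = c(h, h), bbox = c(0, W, 0, W))
}

#' Circular arena with a ring of point landmarks
#'
#' A 1 m diameter (50 cm radius) arena centred on the origin, with 12 evenly
#' spaced point-like landmarks: on the circumference in `distal` mode, or on a
#' ring at 1/8 of the radius (6.25 cm) in `proximal` mode.
#'
#' @param mode `"distal"` or `"proximal"` landmark placement.
#' @return list with elements `env` (an `rsc_environment` with one compartment)
#'   and `landmarks` (an `rsc_landmarks` array).
#' @export
#' @examples
#' arena <- build_circular_arena("distal")
#' arena$landmarks$positions
build_circular_arena <- function(mode = c("distal", "proximal")) {
  mode <- match.arg(mode)
  radius <- 50
  r_lm <- if (mode == "distal") radius else radius / 8
  ang <- seq(0, 330, by = 30)
  pos <- r_lm * heading_to_vec(ang)
  colnames(pos) <- c("x", "y")
  landmarks <- structure(list(positions = pos, mode = mode, count = 12L,
                              angles = ang),
                         class = "rsc_landmarks")
  comps <- list(new_compartment(1L,
                                polygon = radius * heading_to_vec(seq(0, 354, by = 6)),
                                vis_offset = 0, anchor = c(0, 0)))
  env <- new_environment(paste0("circular arena (", mode, " landmarks)"),
                         "circular",
                         boundary = matrix(numeric(0), 0, 4,
                                           dimnames = list(NULL, c("x1", "y1", "x2", "y2"))),
                         walls = matrix(numeric(0), 0, 4,
                                        dimnames = list(NULL, c("x1", "y1", "x2", "y2"))),
                         doors = matrix(numeric(0), 0, 4,
                                        dimnames = list(NULL, c("x1", "y1", "x2", "y2"))),
                         compartments = comps, center = c(0, 0),
                         bbox = c(-radius, radius, -radius, radius),
                         radius = radius)
  list(env = env, landmarks = landmarks)
}

#' Is a point inside the accessible interior?
#'
#' @param env an `rsc_environment`.
#' @param position length-2 numeric `(x, y)` in cm.
#' @return logical scalar.
#' @export
in_environment <- function(env, position) {
  x <- position[1]; y <- position[2]
  switch(env$kind,
    two_comp = ,
    open_field = {
      b <- env$bbox
      x >= b[1] && x <= b[2] && y >= b[3] && y <= b[4]
    },
    circular = sqrt(x^2 + y^2) <= env$radius,
    three_comp = {
      # inside iff, in the sector of its compass angle, the radial distance
      # does not exceed the distance to the opposite wall
      p <- c(x, y) - env$center
      r <- sqrt(sum(p^2))
      if (r < 1e-12) return(TRUE)
      theta <- wrap_angle(atan2(p[1], p[2]) * 180 / pi)
      k <- floor(theta / 120)                     # sector 0, 1, 2
      # wall of sector k: line through the two vertices at 120k and 120(k+1);
      # its inward distance from the centroid is the inradius
      inr <- 120 / (2 * sqrt(3))
      phi <- (theta - (120 * k + 60)) * pi / 180  # angle off the sector bisector
      r <= inr / cos(phi)
    },
    stop("unknown environment kind: ", env$kind))
}

#' Compartment containing a point
#'
#' Uses closed-form geometry per apparatus kind (coordinate comparison for the
#' rectangular builds, compass-sector arithmetic for the triangle). The door
#' gap itself is assigned deterministically: points on the two-compartment
#' partition line belong to compartment 1, and the central open disk of the
#' triangle is split by compass sector.
#'
#' @param env an `rsc_environment`.
#' @param position length-2 numeric `(x, y)` in cm.
#' @return integer compartment id.
#' @export
#' @examples
#' env <- build_two_compartment()
#' compartment_of(env, c(40, 80))   # west -> 1
#' compartment_of(env, c(81, 80))   # just east of the partition -> 2
compartment_of <- function(env, position) {
  if (!in_environment(env, position)) {
    stop(sprintf("position (%g, %g) is outside the environment", position[1], position[2]))
  }
  x <- position[1]; y <- position[2]
  switch(env$kind,
    two_comp = if (x <= 80) 1L else 2L,
    open_field = {
      east <- x >= 60; north <- y >= 60
      if (east && north) 1L else if (east) 2L else if (!north) 3L else 4L
    },
    circular = 1L,
    three_comp = {
      p <- c(x, y) - env$center
      if (sqrt(sum(p^2)) < 1e-12) return(1L)
      theta <- wrap_angle(atan2(p[1], p[2]) * 180 / pi)
      as.integer(floor(theta / 120) + 1L)
    })
}

# Quadrant of a position (NE=1, SE=2, SW=3, NW=4 clockwise), relative to the
# environment centre. Used by the spatial drift analysis in circular arenas.
#' Spatial quadrant of a position
#'
#' @param env an `rsc_environment`.
#' @param x,y coordinates (vectorised) in cm.
#' @return integer vector of quadrant ids 1-4 (NE, SE, SW, NW).
#' @export
quadrant_of <- function(env, x, y) {
  east <- x >= env$center[1]; north <- y >= env$center[2]
  ifelse(east & north, 1L, ifelse(east, 2L, ifelse(!north, 3L, 4L)))
}

#' Local visual direction
#'
#' Direction signalled by the visual environment given the agent's true
#' heading and the compartment's visual offset: the compartment's panorama is
#' rotated by `offset`, so the visually indicated direction is
#' `heading - offset` (mod 360). With offset 0 the visual direction equals the
#' true heading.
#'
#' @param heading true heading, degrees.
#' @param offset compartment visual offset, degrees.
#' @return degrees in `[0, 360)`, vectorised.
#' @export
#' @examples
#' local_visual_direction(30, 0)    # 30
#' local_visual_direction(30, 180)  # 210
local_visual_direction <- function(heading, offset) wrap_angle(heading - offset)

#' Agent pose constructor
#'
#' @param position length-2 numeric `(x, y)` in cm.
#' @param heading degrees, wrapped to `[0, 360)`.
#' @param time seconds.
#' @return list with class `agent_pose`.
#' @export
agent_pose <- function(position, heading, time = 0) {
  structure(list(position = as.numeric(position),
                 heading = wrap_angle(heading), time = time),
            class = "agent_pose")
}

#' Binary landmark-detector rates
#'
#' One detector per landmark, firing at 1 when the landmark falls within the
#' agent's field of view and 0 otherwise. A landmark is in view when the
#' absolute egocentric bearing is at most `fov / 2` (boundary inclusive, so
#' detector support is exactly `fov` wide).
#'
#' @param pose an `agent_pose` (or list with `position` and `heading`).
#' @param landmarks an `rsc_landmarks` array.
#' @param fov field of view in degrees, in `(0, 360]`.
#' @return 0/1 vector, one entry per landmark.
#' @export
landmark_detector_rates <- function(pose, landmarks, fov = 90) {
  stopifnot(fov > 0, fov <= 360)
  dx <- landmarks$positions[, 1] - pose$position[1]
  dy <- landmarks$positions[, 2] - pose$position[2]
  if (any(dx^2 + dy^2 < 1e-12)) {
    stop("agent position coincides with a landmark: bearing undefined")
  }
  bearing <- wrap_angle(atan2(dx, dy) * 180 / pi)
  ego <- circular_diff(bearing, pose$heading)
  as.numeric(abs(ego) <= fov / 2)
}

#' Landmark visibility histogram over head-direction bins
#'
#' Counts, for every landmark, the timesteps at which it is visible, binned by
#' the agent's true heading (60 bins of 6 degrees). Distal landmarks produce
#' peaked histograms (each is visible over a narrow band of headings);
#' proximal landmarks, whose bearing depends strongly on where the agent
#' stands, produce much flatter ones.
#'
#' @param path an `agent_path` (see [random_walk()]).
#' @param landmarks an `rsc_landmarks` array.
#' @param fov field of view in degrees.
#' @param bins number of heading bins (default 60).
#' @return `count x bins` matrix of visibility counts; attribute `bin_centers`
#'   holds the heading bin centres.
#' @export
visibility_histogram <- function(path, landmarks, fov = 90, bins = 60) {
  if (nrow(path) < 1) stop("empty path")
  width <- 360 / bins
  bin <- pmin(floor(wrap_angle(path$heading) / width) + 1, bins)
  out <- matrix(0, landmarks$count, bins)
  for (i in seq_len(landmarks$count)) {
    dx <- landmarks$positions[i, 1] - path$x
    dy <- landmarks$positions[i, 2] - path$y
    bearing <- wrap_angle(atan2(dx, dy) * 180 / pi)
    visible <- abs(circular_diff(bearing, path$heading)) <= fov / 2
    if (any(visible)) {
      tab <- tabulate(bin[visible], nbins = bins)
      out[i, ] <- tab
    }
  }
  attr(out, "bin_centers") <- seq(width / 2, 360 - width / 2, by = width)
  out
}

#' Circular variance of a heading histogram
#'
#' `1 - R`, where `R` is the mean resultant length of the binned distribution;
#' 0 for a point mass, 1 for a uniform histogram.
#'
#' @param counts numeric vector of per-bin counts.
#' @param bin_centers bin centre angles in degrees.
#' @return circular variance in `[0, 1]`.
#' @export
histogram_circular_variance <- function(counts, bin_centers) {
  tot <- sum(counts)
  if (tot <= 0) return(NA_real_)
  s <- sum(counts * sin(bin_centers * pi / 180)) / tot
  c_ <- sum(counts * cos(bin_centers * pi / 180)) / tot
  1 - sqrt(s^2 + c_^2)
}

#' Serialise an environment to a plain config list
#'
#' Produces a nested list (writable as YAML) with walls as `(x1,y1,x2,y2)`
#' rows, compartments as vertex lists plus visual offsets, and landmark
#' coordinates when supplied.
#'
#' @param env an `rsc_environment`.
#' @param landmarks optional `rsc_landmarks`.
#' @return a plain nested list.
#' @export
environment_config <- function(env, landmarks = NULL) {
  cfg <- list(
    name = env$name, kind = env$kind,
    walls = lapply(seq_len(nrow(env$walls)), function(i) as.numeric(env$walls[i, ])),
    doors = lapply(seq_len(nrow(env$doors)), function(i) as.numeric(env$doors[i, ])),
    center = as.numeric(env$center), bbox = as.numeric(env$bbox),
    compartments = lapply(env$compartments, function(cp) {
      list(id = cp$id, vis_offset = cp$vis_offset, odor_label = cp$odor_label,
           anchor = as.numeric(cp$anchor),
           polygon = lapply(seq_len(nrow(cp$polygon)), function(i) as.numeric(cp$polygon[i, ])),
           cue_card = if (is.null(cp$cue_card)) NULL else as.numeric(cp$cue_card))
    }))
  if (!is.null(env$radius)) cfg$radius <- env$radius
  if (!is.null(landmarks)) {
    cfg$landmarks <- list(
      mode = landmarks$mode, count = landmarks$count,
      positions = lapply(seq_len(nrow(landmarks$positions)),
                         function(i) as.numeric(landmarks$positions[i, ])))
  }
  cfg
}

#' Rebuild an environment from a config list
#'
#' Inverse of [environment_config()].
#'
#' @param cfg nested list as produced by [environment_config()] (e.g. read
#'   back from YAML).
#' @return list with `env` and (possibly `NULL`) `landmarks`.
#' @export
environment_from_config <- function(cfg) {
  segmat <- function(rows) {
    m <- if (length(rows)) do.call(rbind, rows) else matrix(numeric(0), 0, 4)
    colnames(m) <- c("x1", "y1", "x2", "y2")
    m
  }
  comps <- lapply(cfg$compartments, function(cp)
    new_compartment(as.integer(cp$id), do.call(rbind, cp$polygon), cp$vis_offset,
                    cue_card = if (is.null(cp$cue_card)) NULL else
                      seg(cp$cue_card[1], cp$cue_card[2], cp$cue_card[3], cp$cue_card[4]),
                    odor_label = cp$odor_label %||% "", anchor = cp$anchor))
  env <- new_environment(cfg$name, cfg$kind, segmat(cfg$walls), segmat(cfg$walls),
                         segmat(cfg$doors), comps, cfg$center, cfg$bbox,
                         radius = cfg$radius)
  lm <- NULL
  if (!is.null(cfg$landmarks)) {
    pos <- do.call(rbind, cfg$landmarks$positions)
    colnames(pos) <- c("x", "y")
    lm <- structure(list(positions = pos, mode = cfg$landmarks$mode,
                         count = as.integer(cfg$landmarks$count),
                         angles = wrap_angle(atan2(pos[, 1], pos[, 2]) * 180 / pi)),
                    class = "rsc_landmarks")
  }
  list(env = env, landmarks = lm)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
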