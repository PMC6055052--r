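test_that("two-compartment apparatus has paper geometry", {
  env <- build_two_compartment()
  expect_length(env$compartments, 2)
  # one central door, 10 cm wide
  expect_equal(nrow(env$doors), 1)
  d <- env$doors[1, ]
  expect_equal(sqrt((d["x2"] - d["x1"])^2 + (d["y2"] - d["y1"])^2),
               10, ignore_attr = TRUE)
  # visual offsets oppose by 180
  offs <- vapply(env$compartments, `[[`, numeric(1), "vis_offset")
  expect_equal(wrap_angle(offs[1] - offs[2]), 180)
  # each compartment is a 160 x 80 rectangle
  for (cp in env$compartments) {
    rng <- apply(cp$polygon, 2, function(v) diff(range(v)))
    expect_setequal(rng, c(80, 160))
  }
  # congruent under 180-degree rotation about the apparatus centre
  p1 <- env$compartments[[1]]$polygon
  p2 <- env$compartments[[2]]$polygon
  rot <- sweep(-sweep(p1, 2, env$center), 2, -env$center)
  key <- function(m) paste(sort(apply(round(m, 6), 1, paste, collapse = ",")),
                           collapse = ";")
  expect_identical(key(rot), key(p2))
})

test_that("three-compartment apparatus has 120 cm walls and a central door", {
  env <- build_three_compartment()
  expect_length(env$compartments, 3)
  # outer walls are the first three wall segments, each 120 cm
  for (i in 1:3) {
    w <- env$walls[i, ]
    expect_equal(sqrt((w["x2"] - w["x1"])^2 + (w["y2"] - w["y1"])^2),
                 120, ignore_attr = TRUE, tolerance = 1e-9)
  }
  # partitions stop 10 cm short of the centroid
  for (i in 4:6) {
    w <- env$walls[i, ]
    expect_equal(sqrt(w["x2"]^2 + w["y2"]^2), 10, ignore_attr = TRUE,
                 tolerance = 1e-9)
  }
  # offsets {0, +120, -120} sum to zero mod 360
  offs <- vapply(env$compartments, `[[`, numeric(1), "vis_offset")
  expect_equal(wrap_angle(sum(offs)), 0)
  expect_setequal(offs, c(0, 120, 240))
})

test_that("open field has four quadrants with 90-degree offset steps", {
  env <- build_open_field()
  expect_length(env$compartments, 4)
  expect_equal(nrow(env$doors), 0)
  offs <- vapply(env$compartments, `[[`, numeric(1), "vis_offset")
  # adjacent quadrants (clockwise order) differ by 90
  expect_true(all(wrap_angle(diff(c(offs, offs[1]))) %in% c(90, 270)))
  # points nudged into each quadrant get 4 distinct ids
  eps <- 1
  probes <- rbind(env$center + c(eps, eps), env$center + c(eps, -eps),
                  env$center - c(eps, eps), env$center + c(-eps, eps))
  ids <- apply(probes, 1, function(p) compartment_of(env, p))
  expect_length(unique(ids), 4)
})

test_that("circular arena places 12 landmarks at the right radii", {
  distal <- build_circular_arena("distal")
  proximal <- build_circular_arena("proximal")
  expect_equal(distal$env$radius, 50)
  for (arena in list(distal, proximal)) {
    expect_equal(arena$landmarks$count, 12L)
    expect_equal(nrow(arena$landmarks$positions), 12)
  }
  rad <- function(lm) sqrt(rowSums(lm$positions^2))
  expect_equal(rad(distal$landmarks), rep(50, 12))
  expect_equal(rad(proximal$landmarks), rep(6.25, 12))
  # even 30-degree spacing: the set is invariant under a 30-degree rotation
  ang <- sort(distal$landmarks$angles)
  expect_equal(wrap_angle(ang + 30)[order(wrap_angle(ang + 30))], ang)
  expect_equal(diff(ang), rep(30, 11))
})

test_that("compartment_of matches a ray-casting oracle on random points", {
  set.seed(42)
  for (env in list(build_two_compartment(), build_three_compartment(),
                   build_open_field())) {
    bb <- env$bbox
    hits <- 0
    while (hits < 250) {
      p <- c(runif(1, bb[1], bb[2]), runif(1, bb[3], bb[4]))
      inside <- vapply(env$compartments, function(cp)
        oracle_point_in_polygon(p[1], p[2], cp$polygon), logical(1))
      if (sum(inside) != 1) next  # skip boundary-ambiguous draws
      hits <- hits + 1
      expect_identical(compartment_of(env, p),
                       env$compartments[[which(inside)]]$id)
    }
  }
})

test_that("compartment_of rejects out-of-bounds points", {
  env <- build_two_compartment()
  expect_error(compartment_of(env, c(-5, 80)), "outside")
  arena <- build_circular_arena()
  expect_error(compartment_of(arena$env, c(51, 0)), "outside")
})

test_that("local visual direction wraps heading minus offset", {
  expect_equal(local_visual_direction(30, 0), 30)
  expect_equal(local_visual_direction(30, 180), 210)
  expect_equal(local_visual_direction(10, 120), 250)
  h <- seq(0, 354, by = 6)
  expect_equal(local_visual_direction(h, 0), h)
  # applying the 180 offset twice returns the original direction
  expect_equal(local_visual_direction(local_visual_direction(h, 180), 180), h)
})

test_that("landmark detectors implement a 90-degree inclusive field of view", {
  arena <- build_circular_arena("distal")
  lm <- arena$landmarks
  # facing landmark 1 (due North at the centre) directly
  r <- landmark_detector_rates(agent_pose(c(0, 0), heading = 0), lm)
  expect_equal(r[1], 1)
  # landmark at exactly 90 degrees egocentric is outside the 90-degree FOV
  r <- landmark_detector_rates(agent_pose(c(0, 0), heading = 270), lm)
  expect_equal(r[1], 0)
  # boundary inclusive: exactly 45 degrees off is visible
  r <- landmark_detector_rates(agent_pose(c(0, 0), heading = 315), lm)
  expect_equal(r[1], 1)
  # from the centre, 3 or 4 of the 30-degree-spaced landmarks are in view
  for (h in seq(0, 355, by = 7)) {
    expect_true(sum(landmark_detector_rates(agent_pose(c(0, 0), h), lm))
                %in% c(3, 4))
  }
  expect_error(landmark_detector_rates(agent_pose(lm$positions[1, ], 0), lm),
               "coincides")
})

test_that("detector output is rotation-equivariant", {
  arena <- build_circular_arena("distal")
  lm <- arena$landmarks
  pose <- agent_pose(c(10, -5), heading = 77)
  base <- landmark_detector_rates(pose, lm)
  for (rot in c(30, 90, 210)) {
    rotated <- lm
    rad <- rot * pi / 180
    R <- matrix(c(cos(rad), sin(rad), -sin(rad), cos(rad)), 2, 2)
    rotated$positions <- lm$positions %*% R  # rotate clockwise by rot
    pos2 <- as.numeric(pose$position %*% R)
    r2 <- landmark_detector_rates(agent_pose(pos2, pose$heading + rot), rotated)
    expect_equal(r2, base)
  }
})

test_that("visibility histograms separate distal from proximal landmarks", {
  # fixed agent at centre under a uniform heading sweep: a distal landmark is
  # visible over a rectangular 90-degree support centred on its bearing
  arena <- build_circular_arena("distal")
  n <- 3600
  path <- data.frame(time = seq_len(n) * 0.01, x = 0, y = 0,
                     heading = seq(0, 360, length.out = n + 1)[-(n + 1)],
                     compartment = 1L, teleport = FALSE)
  attr(path, "dt") <- 0.01
  class(path) <- c("agent_path", "data.frame")
  hist1 <- visibility_histogram(path, arena$landmarks)
  bc <- attr(hist1, "bin_centers")
  support <- which(hist1[1, ] > 0)
  # 90-degree inclusive field of view straddles 16 six-degree bins
  expect_equal(length(support), 16)
  expect_true(all(abs(circular_diff(bc[support], 0)) <= 45))
  # conservation: row total equals number of visible timesteps
  vis_steps <- sum(vapply(seq_len(n), function(t)
    landmark_detector_rates(agent_pose(c(0, 0), path$heading[t]),
                            arena$landmarks)[1], numeric(1)))
  expect_equal(sum(hist1[1, ]), vis_steps)

  # under the same random walk, proximal histograms are flatter
  prox <- build_circular_arena("proximal")
  walk <- random_walk(arena$env, motion_params(duration = 120), seed = 7)
  hd <- visibility_histogram(walk, arena$landmarks)
  hp <- visibility_histogram(walk, prox$landmarks)
  cv_d <- vapply(1:12, function(i)
    histogram_circular_variance(hd[i, ], attr(hd, "bin_centers")), numeric(1))
  cv_p <- vapply(1:12, function(i)
    histogram_circular_variance(hp[i, ], attr(hp, "bin_centers")), numeric(1))
  expect_lt(mean(cv_d), mean(cv_p))
})

test_that("every interior point maps to exactly one compartment", {
  set.seed(11)
  for (env in list(build_two_compartment(), build_three_compartment(),
                   build_open_field())) {
    bb <- env$bbox
    for (k in 1:200) {
      p <- c(runif(1, bb[1], bb[2]), runif(1, bb[3], bb[4]))
      if (!in_environment(env, p)) next
      id <- compartment_of(env, p)
      expect_true(id %in% vapply(env$compartments, `[[`, integer(1), "id"))
    }
  }
})

test_that("environment config round-trips through YAML", {
  arena <- build_circular_arena("proximal")
  cfg <- environment_config(arena$env, arena$landmarks)
  tmp <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, tmp)
  back <- environment_from_config(yaml::read_yaml(tmp))
  expect_equal(back$env$kind, "circular")
  expect_equal(back$env$radius, 50)
  expect_equal(back$landmarks$positions, arena$landmarks$positions,
               tolerance = 1e-6)
  env <- build_two_compartment()
  back2 <- environment_from_config(environment_config(env))$env
  expect_equal(back2$walls, env$walls, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(vapply(back2$compartments, `[[`, numeric(1), "vis_offset"),
               vapply(env$compartments, `[[`, numeric(1), "vis_offset"))
})
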