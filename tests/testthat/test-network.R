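test_that("circular gaussian peaks at its centre and wraps symmetrically", {
  pf <- layer_pfds(60)
  g <- circular_gaussian(93, 20, pf)
  expect_equal(max(g), 1)
  expect_equal(pf[which.max(g)], 93)
  # symmetric about the centre
  gd <- circular_gaussian(90, 25, pf)   # pfds 93 and 87 straddle the centre
  expect_equal(gd[match(123, pf)], gd[match(57, pf)])
  # wrap-around: profile centred near 0 treats 12 and 352 alike
  g0 <- circular_gaussian(2, 20, c(12, 352))
  expect_equal(g0[1], g0[2])
})

test_that("pre-wired weights are angularly homogeneous and aligned", {
  pf <- layer_pfds(60)
  W <- prewire_weights(pf, pf, sigma = 20)
  expect_false(W$plastic)
  expect_true(all(W$values >= 0))
  # pfd-aligned pairs get the maximal weight
  expect_equal(unname(apply(W$values, 2, which.max)), 1:60)
  # symmetric in angular offset
  expect_equal(W$values[10, 20], W$values[20, 10])
  # circular homogeneity: equal row sums across pre cells
  expect_equal(rowSums(W$values), rep(sum(W$values) / 60, 60))
  # unit incoming norm per post cell
  expect_equal(sqrt(colSums(W$values^2)), rep(1, 60))
})

test_that("plastic weight initialisation honours kind and seed", {
  Wz <- init_plastic_weights(60, 100, kind = "zero")
  expect_true(all(Wz$values == 0))
  expect_false(Wz$plastic)
  W1 <- init_plastic_weights(60, 100, seed = 7)
  W2 <- init_plastic_weights(60, 100, seed = 7)
  W3 <- init_plastic_weights(60, 100, seed = 8)
  expect_identical(W1$values, W2$values)
  expect_false(identical(W1$values, W3$values))
  expect_equal(sqrt(colSums(W1$values^2)), rep(1, 100))
  expect_true(W1$plastic)
})

test_that("rates decay to zero without drive and peak at the drive centre", {
  p <- network_params()
  st <- network_state(p, "clamped", seed = 1)
  st$act$rsc <- rep(0.8, p$n_rsc)
  st$rates$rsc <- rep(0.5, p$n_rsc)
  zero <- list(adn = numeric(p$n_adn), vis = numeric(p$n_vis))
  for (t in 1:200) st <- rate_step(st, zero)
  expect_lt(max(st$rates$rsc), 1e-4)
  expect_lt(max(st$rates$conj), 1e-3)

  # constant Gaussian drive held much longer than tau: fixed-point iteration
  # settles on a unimodal RSC profile centred on the drive
  st <- network_state(p, "clamped", seed = 1)
  drive <- list(adn = circular_gaussian(120, p$sigma_input, st$pfds$adn),
                vis = circular_gaussian(120, p$sigma_input, st$pfds$vis))
  for (t in 1:500) st <- rate_step(st, drive)
  expect_equal(st$pfds$rsc[which.max(st$rates$rsc)], 120, tolerance = 7)
  expect_equal(count_peaks(list(rotations = st$pfds$rsc,
                                correlation = st$rates$rsc))$n_peaks, 1)
  expect_true(all(st$rates$rsc >= 0 & st$rates$rsc <= p$rmax))
})

test_that("ENV rates are independent of HD-layer activity", {
  p <- network_params()
  st1 <- network_state(p, "clamped", seed = 2)
  st2 <- network_state(p, "clamped", seed = 2)
  drive_on <- list(adn = circular_gaussian(50, 20, st1$pfds$adn),
                   vis = circular_gaussian(230, 20, st1$pfds$vis))
  drive_off <- list(adn = numeric(p$n_adn), vis = drive_on$vis)
  for (t in 1:300) {
    st1 <- rate_step(st1, drive_on)
    st2 <- rate_step(st2, drive_off)
  }
  expect_equal(st1$rates$env, st2$rates$env, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(st1$rates$conj, st2$rates$conj)))
})

test_that("hebbian update strengthens co-active pairs under a norm budget", {
  W <- init_plastic_weights(4, 3, seed = 1)
  # all-silent rates leave the matrix unchanged
  expect_equal(hebbian_update(W, rep(0, 4), rep(0, 3), 0.1)$values, W$values)
  # a single co-active pre/post pair grows relative to the rest of the column
  pre <- c(0, 1, 0, 0); post <- c(0, 0, 1)
  W2 <- hebbian_update(W, pre, post, 0.5)
  rel_before <- W$values[2, 3] / sum(W$values[, 3])
  rel_after <- W2$values[2, 3] / sum(W2$values[, 3])
  expect_gt(rel_after, rel_before)
  # other columns untouched, updated column renormalised
  expect_equal(W2$values[, 1], W$values[, 1])
  expect_equal(sqrt(colSums(W2$values^2)), rep(1, 3))
  # frozen matrices refuse updates
  Wf <- init_plastic_weights(4, 3, kind = "zero")
  expect_error(hebbian_update(Wf, pre, post, 0.1), "frozen")
})

test_that("attractor bump is stable, tracks velocity, and diffuses with noise", {
  p <- network_params()
  st <- set_bump(network_state(p, "attractor", seed = 1), 90)
  s1 <- st
  for (t in 1:6000) s1 <- adn_attractor_step(s1, 0)  # 60 s
  expect_lt(abs(circular_diff(decode_heading(s1), 90)), 1)

  s2 <- st
  for (t in 1:1000) s2 <- adn_attractor_step(s2, 36)  # 10 s at 36 deg/s
  adv <- (decode_heading(s2) - 90) %% 360 + 0  # should be ~360 (mod)
  travelled <- 360 - abs(circular_diff(decode_heading(s2), 90 + 360))
  expect_lt(abs(circular_diff(decode_heading(s2), (90 + 360) %% 360)),
            0.05 * 360)

  # with noise and no feedback the decoded position random-walks: the spread
  # across seeds grows with time
  drift_at <- function(seed, steps) {
    set.seed(seed)
    s <- st
    om <- rnorm(steps, 0, 15)
    for (t in seq_len(steps)) s <- adn_attractor_step(s, om[t])
    circular_diff(decode_heading(s), 90)
  }
  early <- vapply(1:12, drift_at, numeric(1), steps = 500)
  late <- vapply(1:12, drift_at, numeric(1), steps = 4000)
  expect_gt(stats::var(late), stats::var(early))
})

test_that("run_simulation snapshots and freezes weights as scheduled", {
  env <- build_two_compartment()
  path <- concat_paths(random_walk(env, motion_params(duration = 20), seed = 1),
                       sampling_protocol(env, total = 10, start_time = 20))
  p <- network_params()
  rec <- run_simulation(env, path, p, "clamped", c(0, 20), seed = 1)
  expect_named(rec$snapshots, c("Q1", "Q2", "Q3", "Q4", "final"))
  # weights frozen through the test phase: Q4 (end of learning) == final
  expect_identical(rec$snapshots$Q4$rsc_conj, rec$snapshots$final$rsc_conj)
  expect_identical(rec$snapshots$Q4$conj_rsc, rec$snapshots$final$conj_rsc)
  # with zero learning rate weights never leave their initialisation
  rec0 <- run_simulation(env, path, network_params(learn_rate = 0),
                         "clamped", c(0, 20), seed = 1)
  init <- init_plastic_weights(p$n_rsc, p$n_conj, p$init_scale, seed = 1)
  expect_equal(rec0$snapshots$Q1$rsc_conj, init$values)
  expect_equal(rec0$snapshots$final$rsc_conj, init$values)
  # HD -> ENV stays identically zero even with learning on
  expect_true(all(rec$weights$rsc_env$values == 0))
  # schedule outside the path duration errors
  expect_error(run_simulation(env, path, p, "clamped", c(0, 100)),
               "schedule")
})

test_that("rates and plastic norms stay bounded throughout a simulation", {
  env <- build_two_compartment()
  path <- concat_paths(random_walk(env, motion_params(duration = 15), seed = 2),
                       sampling_protocol(env, total = 6, start_time = 15))
  rec <- run_simulation(env, path, network_params(), "clamped", c(0, 15),
                        seed = 2, record_every = 5)
  for (ly in c("adn", "rsc", "conj", "env")) {
    R <- rec$rates_test[[ly]]
    expect_true(all(R >= 0 & R <= 1 + 1e-12))
  }
  for (sn in c("Q1", "Q3", "final")) {
    expect_equal(sqrt(colSums(rec$snapshots[[sn]]$rsc_conj^2)), rep(1, 100),
                 tolerance = 1e-9)
    expect_equal(sqrt(colSums(rec$snapshots[[sn]]$conj_rsc^2)), rep(1, 60),
                 tolerance = 1e-9)
  }
})

test_that("identical seeds reproduce a simulation exactly", {
  env <- build_three_compartment()
  path <- random_walk(env, motion_params(duration = 10), seed = 4)
  r1 <- run_simulation(env, path, network_params(), "clamped", c(0, 8), seed = 4)
  r2 <- run_simulation(env, path, network_params(), "clamped", c(0, 8), seed = 4)
  expect_identical(r1$rates_test, r2$rates_test)
  expect_identical(r1$weights$rsc_conj$values, r2$weights$rsc_conj$values)
})
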