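# Layered firing-rate network: ADN head-direction ring (clamped Gaussian bump
# or a continuous ring attractor), RSC HD relay layer, a bidirectional layer
# split into CONJ (visual + plastic HD inputs) and ENV (visual inputs only)
# subpopulations, and a VIS layer carrying the environment-indicated
# direction (a Gaussian bump over direction cells, or 12 binary landmark
# detectors in the circular-arena experiments).
#
# Dynamics are a leaky integrator per cell,
#   tau * da/dt = -a + excitation - inhibition,
# with a rectified-saturating transfer r = rmax * tanh(max(a, 0) / rmax) and
# subtractive inhibition proportional to the mean rate of the local layer.
# Plastic weights follow a Hebbian rule with multiplicative per-postsynaptic
# normalisation (each post cell's incoming weight vector is rescaled to unit
# Euclidean norm after every update), which bounds growth and makes
# co-activation strengthen a synapse relative to the others on the same cell.

#' Network parameters
#'
#' All tunable constants of the rate model. The published description leaves
#' the precise equations unspecified, so these are package defaults chosen so
#' that the network holds a single activity bump per ring, tracks the
#' protocol's 36 deg/s rotation, and self-organises within a 600 s session;
#' see the methods vignette for the reasoning behind each value.
#'
#' @param n_adn,n_rsc,n_vis,n_conj,n_env cells per layer (VIS becomes 12
#'   binary detectors in landmark mode regardless of `n_vis`).
#' @param sigma_adn_rsc width (deg) of the pre-wired ADN to RSC Gaussian
#'   weight profile.
#' @param sigma_vis_bd width (deg) of the pre-wired VIS to bidirectional
#'   weights; 20 for the compartment experiments, 40 in the open field.
#' @param sigma_input width (deg) of the Gaussian activity bump clamped onto
#'   the ADN ring.
#' @param sigma_input_vis width (deg) of the Gaussian bump clamped onto the
#'   VIS ring; widened to 40 together with `sigma_vis_bd` in the open-field
#'   simulation.
#' @param sigma_rec width (deg) of the ADN ring-attractor recurrent profile.
#' @param tau rate time constant, seconds.
#' @param dt Euler step, seconds (shared with the trajectory).
#' @param rmax saturation rate (transfer is `rmax * tanh(max(a,0)/rmax)`).
#' @param g_adn_rsc,g_vis_bd,g_hd_conj,g_fb_rsc,g_rec,g_rsc_adn connection
#'   gains: ADN->RSC, VIS->bidirectional, RSC->CONJ, bidirectional->RSC
#'   feedback, ADN recurrent, and RSC->ADN feedback.
#' @param k_rsc,k_bd,k_adn subtractive inhibition gains (input is reduced by
#'   `k * mean(layer rate)`).
#' @param learn_rate Hebbian rate per step.
#' @param init_scale upper bound of the uniform random initial plastic weights.
#' @param reverse_plasticity learn the bidirectional-to-RSC return projection
#'   as well (the forward HD-to-CONJ path alone suffices for bidirectional
#'   tuning; the return path is what corrects the attractor).
#' @param noise_sd path-integration noise, deg/s (attractor mode).
#' @return list of class `network_params`.
#' @export
network_params <- function(n_adn = 60, n_rsc = 60, n_vis = 60,
                           n_conj = 100, n_env = 100,
                           sigma_adn_rsc = 20, sigma_vis_bd = 20,
                           sigma_input = 20, sigma_input_vis = sigma_input,
                           sigma_rec = 20,
                           tau = 0.05, dt = 0.01, rmax = 1,
                           g_adn_rsc = 1.2, g_vis_bd = 1.2, g_hd_conj = 0.7,
                           g_fb_rsc = 0.15, g_rec = 1.3, g_rsc_adn = 0.3,
                           k_rsc = 4, k_bd = 8, k_adn = 10,
                           learn_rate = 2e-4, init_scale = 1,
                           reverse_plasticity = TRUE, noise_sd = 15) {
  p <- list(n_adn = n_adn, n_rsc = n_rsc, n_vis = n_vis, n_conj = n_conj,
            n_env = n_env, sigma_adn_rsc = sigma_adn_rsc,
            sigma_vis_bd = sigma_vis_bd, sigma_input = sigma_input,
            sigma_input_vis = sigma_input_vis,
            sigma_rec = sigma_rec, tau = tau, dt = dt, rmax = rmax,
            g_adn_rsc = g_adn_rsc, g_vis_bd = g_vis_bd, g_hd_conj = g_hd_conj,
            g_fb_rsc = g_fb_rsc, g_rec = g_rec, g_rsc_adn = g_rsc_adn,
            k_rsc = k_rsc, k_bd = k_bd, k_adn = k_adn,
            learn_rate = learn_rate, init_scale = init_scale,
            reverse_plasticity = reverse_plasticity, noise_sd = noise_sd)
  stopifnot(all(vapply(p[c("sigma_adn_rsc", "sigma_vis_bd", "sigma_input",
                           "sigma_rec", "tau", "dt", "rmax")],
                       function(v) is.numeric(v) && v > 0, TRUE)))
  structure(p, class = "network_params")
}

#' Evenly spaced preferred firing directions
#'
#' @param n number of cells.
#' @return angles in degrees: `360 * (0:(n-1)) / n + 180/n` (bin centres, so
#'   60 cells get PFDs 3, 9, ..., 357).
#' @export
layer_pfds <- function(n) 360 * (seq_len(n) - 1) / n + 180 / n

#' Circular Gaussian activity profile
#'
#' `exp(-d^2 / (2 sigma^2))` with `d` the wrapped angular distance from
#' `center` to each preferred direction; maximal (1) at `pfd == center`.
#'
#' @param center bump centre, degrees.
#' @param sigma width, degrees.
#' @param pfds vector of preferred directions, degrees.
#' @return activity vector in `[0, 1]`, same length as `pfds`.
#' @export
#' @examples
#' circular_gaussian(90, 20, layer_pfds(60))
circular_gaussian <- function(center, sigma, pfds) {
  stopifnot(sigma > 0)
  d <- circular_diff(pfds, center)
  exp(-d^2 / (2 * sigma^2))
}

#' Pre-wired Gaussian weight matrix
#'
#' Connection strength between every pre/post pair is a Gaussian function of
#' the wrapped difference between their preferred directions, as used for the
#' ADN-to-RSC and VIS-to-bidirectional projections and the ADN recurrent
#' collaterals. Each postsynaptic cell's incoming vector is normalised to unit
#' Euclidean norm (then scaled by `gain`) so that pre-wired and learned
#' projections are on a common scale.
#'
#' @param pre_pfds,post_pfds preferred directions of the two layers, degrees.
#' @param sigma Gaussian width, degrees.
#' @param gain scalar multiplier applied after normalisation.
#' @param normalize normalise each column (post cell) to unit norm.
#' @return a `weight_matrix` (list with `values` (pre x post), `plastic =
#'   FALSE`, `label`, `pre_pfds`, `post_pfds`).
#' @export
prewire_weights <- function(pre_pfds, post_pfds, sigma, gain = 1,
                            normalize = TRUE, label = "prewired") {
  W <- outer(pre_pfds, post_pfds,
             function(a, b) exp(-circular_diff(a, b)^2 / (2 * sigma^2)))
  if (normalize) W <- normalize_columns(W)
  new_weight_matrix(gain * W, plastic = FALSE, label = label,
                    pre_pfds = pre_pfds, post_pfds = post_pfds)
}

#' Initialise a plastic weight matrix
#'
#' Random uniform weights in `[0, scale]`, normalised to unit incoming norm
#' per postsynaptic cell, as used for the HD-to-CONJ and bidirectional-to-RSC
#' projections before learning. `kind = "zero"` produces the all-zero, frozen
#' matrix used for HD-to-ENV (ENV cells receive no HD input, ever).
#'
#' @param n_pre,n_post dimensions.
#' @param scale upper bound of the uniform initial values.
#' @param seed integer RNG seed.
#' @param kind `"random"` (plastic) or `"zero"` (frozen at zero).
#' @param label connection name.
#' @return a `weight_matrix`.
#' @export
init_plastic_weights <- function(n_pre, n_post, scale = 1, seed = 1,
                                 kind = c("random", "zero"), label = "plastic") {
  kind <- match.arg(kind)
  stopifnot(scale >= 0)
  if (kind == "zero") {
    return(new_weight_matrix(matrix(0, n_pre, n_post), plastic = FALSE,
                             label = label))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  W <- matrix(stats::runif(n_pre * n_post, 0, scale), n_pre, n_post)
  new_weight_matrix(normalize_columns(W), plastic = TRUE, label = label)
}

new_weight_matrix <- function(values, plastic, label,
                              pre_pfds = NULL, post_pfds = NULL) {
  structure(list(values = values, plastic = plastic, label = label,
                 pre_pfds = pre_pfds, post_pfds = post_pfds),
            class = "weight_matrix")
}

#' @export
print.weight_matrix <- function(x, ...) {
  cat(sprintf("<weight_matrix '%s': %d x %d, %s>\n", x$label,
              nrow(x$values), ncol(x$values),
              if (x$plastic) "plastic" else "frozen"))
  invisible(x)
}

# rescale every column to unit Euclidean norm (zero columns left untouched)
normalize_columns <- function(W) {
  nrm <- sqrt(.colSums(W * W, nrow(W), ncol(W)))
  nrm[nrm == 0] <- 1
  W * rep(1 / nrm, each = nrow(W))
}

#' Hebbian update with multiplicative normalisation
#'
#' `W <- W + learn_rate * pre %o% post`, followed by rescaling of each
#' postsynaptic cell's incoming vector to unit Euclidean norm. The
#' normalisation implements synaptic competition: a co-active pair grows at
#' the expense of the other synapses on the same cell, and uncorrelated
#' inputs decay relative to correlated ones.
#'
#' @param W a plastic `weight_matrix`.
#' @param pre_rates,post_rates firing-rate vectors.
#' @param learn_rate Hebbian rate.
#' @return the updated `weight_matrix`.
#' @export
hebbian_update <- function(W, pre_rates, post_rates, learn_rate) {
  if (!inherits(W, "weight_matrix")) stop("W must be a weight_matrix")
  if (!W$plastic) stop(sprintf("weight matrix '%s' is frozen", W$label))
  W$values <- normalize_columns(W$values + learn_rate * outer(pre_rates, post_rates))
  W
}

# transfer function: rectified, saturating at rmax
.transfer <- function(a, rmax) rmax * tanh(pmax(a, 0) / rmax)

# one leaky-integrator Euler step for a layer's activations
.leaky_step <- function(a, input, dt_over_tau) a + dt_over_tau * (input - a)

#' Construct network state
#'
#' Builds all layers and connections for a simulation mode. In `clamped` mode
#' the ADN and VIS rings are driven directly by Gaussian bumps; in
#' `attractor` mode the ADN ring is recurrent (path-integrating) and the VIS
#' layer holds 12 binary landmark detectors whose projections to the
#' bidirectional layer are plastic.
#'
#' @param params a `network_params` object.
#' @param mode `"clamped"` or `"attractor"`.
#' @param seed integer seed for the random initial plastic weights.
#' @return list of class `network_state` with `weights` (list of
#'   `weight_matrix`), `act`/`rates` per layer, `pfds` per layer, `mode`.
#' @export
network_state <- function(params = network_params(),
                          mode = c("clamped", "attractor"), seed = 1) {
  mode <- match.arg(mode)
  p <- params
  n_vis <- if (mode == "attractor") 12L else p$n_vis
  pfds <- list(adn = layer_pfds(p$n_adn), rsc = layer_pfds(p$n_rsc),
               vis = layer_pfds(n_vis), conj = layer_pfds(p$n_conj),
               env = layer_pfds(p$n_env))
  w <- list(
    adn_rsc = prewire_weights(pfds$adn, pfds$rsc, p$sigma_adn_rsc,
                              gain = p$g_adn_rsc, label = "ADN->RSC"),
    rsc_conj = init_plastic_weights(p$n_rsc, p$n_conj, p$init_scale,
                                    seed = seed, label = "RSC->CONJ"),
    rsc_env = init_plastic_weights(p$n_rsc, p$n_env, kind = "zero",
                                   label = "RSC->ENV"),
    conj_rsc = init_plastic_weights(p$n_conj, p$n_rsc, p$init_scale,
                                    seed = seed + 1, label = "CONJ->RSC"),
    env_rsc = init_plastic_weights(p$n_env, p$n_rsc, p$init_scale,
                                   seed = seed + 2, label = "ENV->RSC"))
  if (mode == "clamped") {
    w$vis_conj <- prewire_weights(pfds$vis, pfds$conj, p$sigma_vis_bd,
                                  gain = p$g_vis_bd, label = "VIS->CONJ")
    w$vis_env <- prewire_weights(pfds$vis, pfds$env, p$sigma_vis_bd,
                                 gain = p$g_vis_bd, label = "VIS->ENV")
  } else {
    w$vis_conj <- init_plastic_weights(n_vis, p$n_conj, p$init_scale,
                                       seed = seed + 3, label = "VIS->CONJ")
    w$vis_env <- init_plastic_weights(n_vis, p$n_env, p$init_scale,
                                      seed = seed + 4, label = "VIS->ENV")
    w$adn_rec <- prewire_weights(pfds$adn, pfds$adn, p$sigma_rec,
                                 gain = p$g_rec, label = "ADN recurrent")
    w$rsc_adn <- prewire_weights(pfds$rsc, pfds$adn, p$sigma_adn_rsc,
                                 gain = p$g_rsc_adn, label = "RSC->ADN")
  }
  if (!p$reverse_plasticity) {
    w$conj_rsc$plastic <- FALSE
    w$env_rsc$plastic <- FALSE
  }
  zero <- function(n) numeric(n)
  structure(list(
    params = p, mode = mode, pfds = pfds, weights = w,
    act = list(adn = zero(p$n_adn), rsc = zero(p$n_rsc),
               conj = zero(p$n_conj), env = zero(p$n_env)),
    rates = list(adn = zero(p$n_adn), vis = zero(n_vis), rsc = zero(p$n_rsc),
                 conj = zero(p$n_conj), env = zero(p$n_env)),
    time = 0), class = "network_state")
}

#' One synchronous rate step (clamped drive)
#'
#' Advances the RSC and bidirectional layers by one Euler step given clamped
#' ADN and VIS rate vectors. RSC receives feed-forward ADN drive plus
#' feedback from both bidirectional subpopulations; CONJ receives VIS and RSC
#' input; ENV receives VIS input only. Inhibition is subtractive within the
#' RSC layer and within the combined bidirectional layer.
#'
#' @param state a `network_state`.
#' @param drive list with elements `adn` and `vis` (rate vectors).
#' @param params optional override of `state$params`.
#' @return the updated `network_state` (rates rectified-saturating, so always
#'   in `[0, rmax]`).
#' @export
rate_step <- function(state, drive, params = state$params) {
  p <- params
  w <- state$weights
  if (length(drive$adn) != p$n_adn ||
      length(drive$vis) != nrow(w$vis_conj$values)) {
    stop("drive dimensions do not match layer sizes")
  }
  dtt <- p$dt / p$tau
  r <- state$rates
  inh_rsc <- p$k_rsc * mean(r$rsc)
  in_rsc <- crossprod(w$adn_rsc$values, drive$adn)[, 1] +
    p$g_fb_rsc * (crossprod(w$conj_rsc$values, r$conj)[, 1] +
                    crossprod(w$env_rsc$values, r$env)[, 1]) - inh_rsc
  in_conj <- crossprod(w$vis_conj$values, drive$vis)[, 1] +
    p$g_hd_conj * crossprod(w$rsc_conj$values, r$rsc)[, 1] -
    p$k_bd * mean(r$conj)
  in_env <- crossprod(w$vis_env$values, drive$vis)[, 1] - p$k_bd * mean(r$env)
  state$act$rsc <- .leaky_step(state$act$rsc, in_rsc, dtt)
  state$act$conj <- .leaky_step(state$act$conj, in_conj, dtt)
  state$act$env <- .leaky_step(state$act$env, in_env, dtt)
  state$rates$adn <- drive$adn
  state$rates$vis <- drive$vis
  state$rates$rsc <- .transfer(state$act$rsc, p$rmax)
  state$rates$conj <- .transfer(state$act$conj, p$rmax)
  state$rates$env <- .transfer(state$act$env, p$rmax)
  state$time <- state$time + p$dt
  state
}

# fractional circular shift of a ring profile by `s` bins (positive = toward
# higher preferred directions), linear interpolation between neighbours
shift_ring <- function(a, s) {
  n <- length(a)
  k <- floor(s)
  f <- s - k
  i <- seq_len(n)
  lo <- ((i - 1 - k) %% n) + 1
  hi <- ((i - 2 - k) %% n) + 1
  (1 - f) * a[lo] + f * a[hi]
}

#' One step of the ADN ring attractor
#'
#' Recurrent Gaussian excitation plus global (mean-rate) inhibition sustains
#' a single activity bump; the bump is advanced by `angular_velocity * dt`
#' per step by rotating the activation profile (path integration), and an
#' optional feedback input from the RSC HD layer is added, which is what lets
#' learned visual landmarks correct integration drift.
#'
#' @param state a `network_state` built in `attractor` mode.
#' @param angular_velocity signed turning speed, degrees/s (noise included by
#'   the caller).
#' @param feedback input vector to the ADN ring (e.g. scaled RSC rates
#'   through the topographic RSC->ADN map); 0 for none.
#' @param params optional override of `state$params`.
#' @return the updated `network_state`.
#' @export
adn_attractor_step <- function(state, angular_velocity, feedback = 0,
                               params = state$params) {
  p <- params
  w <- state$weights
  dtt <- p$dt / p$tau
  r <- state$rates$adn
  input <- crossprod(w$adn_rec$values, r)[, 1] + feedback - p$k_adn * mean(r)
  a <- .leaky_step(state$act$adn, input, dtt)
  bin <- 360 / p$n_adn
  state$act$adn <- shift_ring(a, angular_velocity * p$dt / bin)
  state$rates$adn <- .transfer(state$act$adn, p$rmax)
  state$time <- state$time + p$dt
  state
}

#' Decode the ADN bump position
#'
#' Circular mean of preferred directions weighted by current ADN rates.
#'
#' @param state a `network_state`.
#' @return degrees in `[0, 360)`.
#' @export
decode_heading <- function(state) {
  circular_mean(state$pfds$adn, state$rates$adn)
}

#' Seed an attractor state with a bump at a given heading
#'
#' @param state a `network_state` in attractor mode.
#' @param heading bump centre, degrees.
#' @return the state with ADN activation/rates initialised.
#' @export
set_bump <- function(state, heading) {
  prof <- circular_gaussian(heading, state$params$sigma_input, state$pfds$adn)
  state$act$adn <- 2 * prof
  state$rates$adn <- .transfer(state$act$adn, state$params$rmax)
  state
}
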