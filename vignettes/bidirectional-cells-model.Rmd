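---
title: "A network model of bidirectional directional cells in retrosplenial cortex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A network model of bidirectional directional cells in retrosplenial cortex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rschd)
```

## The scientific problem

Head-direction (HD) cells fire whenever the animal faces one particular
allocentric direction. The HD signal is maintained by angular path
integration, which drifts, so it must be anchored to stable environmental
landmarks — yet the stability of a landmark can only be judged against the
very sense of direction it is supposed to anchor. Retrosplenial cortex (RSC),
which relays visual information to the HD system, contains — besides ordinary
HD cells — two stranger cell classes recorded in a two-compartment apparatus
whose halves are visual 180° rotations of one another:

* **between-compartment (BC) cells** — unimodal in each compartment, but the
  preferred firing direction (PFD) flips 180° between compartments, so the
  whole-apparatus tuning curve is bimodal;
* **within-compartment (WC) cells** — bimodal inside a single compartment,
  with a dominant pole that flips between compartments.

Both classes lose tuning in an open field, while HD cells do not. `rschd`
implements a firing-rate network in which these properties *self-organise*
from Hebbian plasticity between an HD ring signal and visually driven
direction cells, and then uses the same circuit to show how distal — but not
proximal — landmarks can anchor a drifting HD signal.

## The network

Five layers of rate neurons, each cell with a preferred direction on the
circle:

* **ADN** (anterodorsal thalamic) HD ring — the ascending HD signal. In the
  compartment experiments it is clamped to a circular-Gaussian bump centred
  on the true heading (σ = 20°); in the landmark experiments it is a
  continuous ring attractor integrating a noisy angular-velocity signal.
* **RSC HD layer** — no recurrent collaterals; receives pre-wired
  Gaussian-profile weights from ADN plus plastic feedback from the
  bidirectional layer, with subtractive local inhibition.
* **Bidirectional layer** — 100 **CONJ** cells (pre-wired visual input *and*
  plastic HD input) and 100 **ENV** cells (visual input only; their HD input
  is identically zero and frozen). Both project back to the RSC HD layer
  through plastic weights.
* **VIS layer** — direction as indicated by the local visual scene: a
  Gaussian bump at `heading − compartment offset` (offsets 0/180° in the
  two-compartment box, 0/±120° in the triangle, 0/90/180/270° across
  open-field quadrants). In the landmark experiments it is replaced by 12
  binary detectors that fire 1 whenever their landmark falls within a 90°
  field of view.

Every cell obeys a leaky integrator `τ da/dt = −a + input − inhibition` with
`τ = 50 ms`, Euler step `dt = 10 ms`, and a rectified-saturating transfer
`r = tanh(max(a, 0))`. Inhibition is subtractive and proportional to the mean
rate of the cell's own (sub)population; keeping separate inhibitory pools for
the CONJ and ENV subpopulations lets ENV cells stay active when CONJ cells
are strongly driven by their extra HD input, which matters in the
sparse-input landmark mode.

Plastic connections follow a Hebbian rule with multiplicative per-cell
normalisation: `ΔW[i,j] = η · pre_i · post_j`, after which each postsynaptic
cell's incoming weight vector is rescaled to unit Euclidean norm. The
normalisation bounds growth and implements synaptic competition: co-active
inputs grow at the expense of the other synapses on the same cell.

### Why the constants have the values they do

The published model description states the architecture but not the
equations (they reside in unavailable supplementary material), so all
dynamical constants here are the package's own, chosen during model design —
before any result-level comparisons — so that each subsystem behaves
sensibly in isolation:

* `sigma_input = sigma_adn_rsc = sigma_vis_bd = 20°` — matching the one
  printed width (the open-field run raises the VIS→bidirectional width to
  40°, as stated for that simulation);
* gains `g_adn_rsc = g_vis_bd = 1.2` place the peak feed-forward drive a
  little above saturation, giving robust but graded bumps;
* `g_hd_conj = 0.7` makes the learned HD drive to a CONJ cell roughly half
  its visual drive, so the HD-alone pole of a WC cell is present but weaker
  — the observed peak asymmetry;
* inhibition gains (`k_rsc = 4`, `k_bd = 8`, `k_adn = 10`) are set high
  enough to cancel the common-mode gain of nonnegative random weight
  matrices; below this the layer locks into a saturated state with no
  direction selectivity;
* `learn_rate = 2e-4` balances two failure modes: much slower and the random
  initial weights are never erased (no bimodal structure emerges in 600 s);
  much faster and normalisation-induced forgetting erases the association
  made in one compartment while the agent dwells in the other;
* bidirectional→RSC feedback is `g_fb_rsc = 0.15` in the compartment
  experiments (strong enough to be learned, weak enough that RSC HD cells
  stay unimodal against the ambiguous 180°-apart feedback) and `0.3` in the
  landmark experiments, where that feedback *is* the corrective pathway and
  must compete with path-integration noise;
* the attractor constants (`g_rec = 1.3`, `k_adn = 10`, `σ_rec = 20°`) give
  a single stable bump that tracks a 36°/s rotation with ≈1.4% error and
  drifts < 1°/min in the absence of input.

## Trajectories

The learning phase uses a **random-waypoint walk**: the agent draws targets
uniformly over the accessible interior, steers toward them at 20 cm/s with a
bounded turning rate (180°/s) and Gaussian heading noise (20°/√s), and routes
through the door when a partition blocks the straight line. A pure
heading-diffusion walk was tried first and rejected: through a 10 cm door it
essentially never changes compartment within 600 s, and the model then
learns only one compartment's HD–visual relationship. The waypoint walk
yields balanced compartment occupancy, tens of door transitions per session,
and full heading coverage in every compartment.

The test phase uses the fixed-rotation protocol: weights frozen, the agent
rotating on the spot at 36°/s at one point per compartment, 30 s split
equally across compartments (15 s each for two compartments, 10 s for
three). A 540° sweep cannot dwell in every 6° bin exactly equally (bins
covered twice by the extra half-turn get double dwell), but tuning curves
are per-bin *means*, so the residual unevenness is immaterial.

In the landmark experiments the test phase is instead 120 s of continued
free exploration with all learning off, and ADN is driven by the true
per-step heading derivative plus zero-mean Gaussian noise (default
`noise_sd = 15°/s`). That value was fixed a priori so that unaided
integration drifts by a few tens of degrees over a 600 s session — enough
drift for landmark correction to be measurable, small enough that early
Hebbian associations form near the true heading.

## What the simulations show

* **Two-compartment (600 s + 30 s protocol)**: HD→CONJ weight columns become
  bimodal with modes ≈180° apart; ENV cells flip their per-compartment PFD
  by ≈180°; the layer-mean CONJ whole-apparatus autocorrelation peaks at
  180°; ADN and RSC HD cells stay unimodal with compartment-invariant PFDs.
  Weight development is front-loaded: the Q1 snapshot already correlates
  ≈0.9 with the final weights.
* **Three-compartment**: the same quantities become three-fold (ENV PFD
  steps of ≈120°, trimodal autocorrelations for most CONJ cells). As in the
  recordings this is less uniform than the two-compartment case: the three
  compartment associations compete for the same normalised weight budget,
  and a minority of CONJ cells end up dominated by one or two of them. The
  dominant pole of a WC cell is always the visually aligned one, and
  within-compartment bidirectionality often matures in one compartment
  before the other.
* **Open field (σ = 40)**: four 90°-spaced associations under doubled width
  overlap so heavily that modulation depth collapses; CONJ and ENV cells
  classify as untuned while HD cells are unaffected. Three related overrides
  implement the widened visual pathway: the VIS bump and VIS→bidirectional
  weight width rise to 40°, the visual gain doubles (widening an
  unnormalised Gaussian weight profile carries more total drive; the package
  normalises weights, so the drive increase is folded into the gain), and
  bidirectional-layer competition is nearly removed (`k_bd = 0.1`) —
  strong subtractive inhibition would re-sharpen each quadrant's curve and
  defeat the additive-overlap mechanism, which presupposes that the tuning
  curve is (approximately) the plain sum of the per-compartment Gaussians.
  The same arithmetic is available analytically through `capacity_tuning()`:
  the sum of N evenly spaced Gaussians loses modulation depth monotonically
  in both N and σ, down to the level where the curve is effectively flat.
* **Landmark arena**: with distal landmarks (on the 50 cm-radius
  circumference) each detector fires over a narrow, position-independent
  band of headings, so Hebbian learning wires detector→bidirectional→RSC→ADN
  loops that confine attractor drift to roughly the width of a tuning curve
  bin or two. With the same 12 landmarks at 1/8 radius, detector activity is
  nearly uniform in heading (parallax), the learned loop carries no
  directional information, and the accumulated drift is several times
  larger — often worse than integration noise alone, because the spurious
  associations actively pull the bump.

## Numerical and design notes

* Angles are degrees in `[0, 360)`, 0 = North, clockwise positive; all
  wrapping is mod 360 and signed differences live in `(−180, 180]`.
* Tuning curves: 60 bins of 6°, per-bin mean rate, circular 5-bin moving
  average (mass-conserving). Empty bins — impossible under the rotation
  protocol but possible in short free-running windows — are filled by
  circular linear interpolation and flagged.
* The PFD is the rate-weighted circular mean of bin centres
  (`atan2(Σ r sin x, Σ r cos x)`); it errors, rather than returning a
  number, when the resultant is numerically zero (uniform or perfectly
  balanced bimodal curves).
* Peak counting works on the rotational autocorrelation and keeps circular
  local maxima whose topographic prominence exceeds 0.1 of the profile
  range; ties on plateaus count once. The same prominence rule is used when
  measuring peak asymmetry on the tuning curve itself.
* Cell classification thresholds (modulation depth ≥ 0.4; per-compartment
  PFDs "stable" within 30°) are package conventions operationalising the
  verbal criteria; they are deliberately exposed as arguments.
* The bump of the ring attractor is advanced each step by rotating the
  activation profile by `ω·dt` with fractional circular interpolation; the
  interpolation's slight smoothing is counteracted by the recurrent
  dynamics, and tracking error at protocol speed is ≈1.4%.
* `run_simulation()` stores test-phase rates at full resolution and
  learning-phase rates every 10th step; with 60 s quartiles that still gives
  ≥1,500 samples per quartile for the development analysis.
* Determinism: a run is fully determined by (config, seed); the generator
  restores the caller's RNG state.

## Problem sizes used by the test suite

Unit and property tests run the full pipeline at reduced duration (60 s
learning) with majority-style assertions, which keeps the default
`devtools::test()` run light. The acceptance suite and
`scripts/acceptance.R` run the actual study conditions — 600 s learning,
30 s rotation protocol, 120 s frozen landmark test — once per apparatus.

## Known limitations

* The walk is kinematic, not behavioural: no thigmotaxis, dwell-time
  statistics, or speed modulation; heading statistics in a compartment are
  shaped by the waypoint geometry.
* The network's exact equations are declared, not derived from the source
  description; quantities that depend on fine dynamics (absolute firing
  rates, exact asymmetry ratios, drift magnitudes) are calibrated only at
  the level of qualitative orderings.
* The signed layer-mean drift of the landmark experiments is the realisation
  of a noise-driven random walk: its sign and exact magnitude vary across
  seeds; only the distal < proximal ordering and the stabilisation of distal
  drift across test windows are stable properties.
* Symmetry breaking between compartments (the animal's olfactory/contextual
  knowledge) is wired in by construction, dark-condition persistence and
  cue-conflict protocols are not simulated, and VIS inputs are hand-wired
  rather than learned from sensory cortex.
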