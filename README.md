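# rschd

A firing-rate network model of how retrosplenial cortex (RSC) couples the
head-direction (HD) system to the visual environment, for computational and
systems neuroscientists studying directional coding.

In a two-compartment box whose halves are visual 180° rotations of one
another, RSC recordings show — besides ordinary HD cells — *bidirectional*
cells: between-compartment (BC) cells whose single preferred firing direction
(PFD) flips 180° at the doorway, and within-compartment (WC) cells that are
bimodal even inside one compartment, with a dominant pole that flips. `rschd`
implements the network in which these properties self-organise:

* a clamped (or ring-attractor) **ADN** HD signal feeds an **RSC HD** layer
  through pre-wired Gaussian weights `W[i,j] ∝ exp(−d(θ_i, θ_j)² / 2σ²)`;
* a **VIS** layer signals direction as indicated by the local visual scene
  (rotated by the compartment's symmetry offset), pre-wired onto a
  bidirectional layer of **CONJ** cells (visual + plastic HD input) and
  **ENV** cells (visual input only);
* plastic connections evolve by Hebbian learning with multiplicative
  per-cell normalisation, `ΔW[i,j] = η·r_pre,i·r_post,j` followed by
  rescaling each postsynaptic cell's incoming vector to unit norm;
* tuning is analysed exactly as in the recordings: 6°-binned, 5-bin-smoothed
  tuning curves; PFD as the rate-weighted circular mean
  `atan2(Σ rᵢ sin xᵢ, Σ rᵢ cos xᵢ)`; peak counts from the rotational
  autocorrelation.

Hebbian co-activation of one visual direction with two (or three) HD
directions makes CONJ cells bimodal (trimodal) while ENV cells flip; in a
four-fold-symmetric open field the overlapping associations erase tuning
specificity; and in a circular arena with 12 landmark-detector inputs the
same circuit anchors a noisy path-integrating HD attractor when landmarks
are distal but not when they are proximal (parallax).

## Worked example

A reduced two-compartment session (60 s of exploration instead of the full
600 s, then the 30 s fixed-rotation test protocol):

```r
library(rschd)
rep <- run_experiment(experiment_config("two_comp", duration = 60, seed = 1))
print(rep)
#> <experiment_report: two_comp, seed 1>
#>   adn: HD_like=60
#>   rsc: HD_like=60
#>   conj: BC_like=80, WC_like=20
#>   env: BC_like=100
```

All 60 thalamic (ADN) and 60 retrosplenial HD cells keep a single,
compartment-invariant PFD. All 100 ENV cells are classified BC-like: unimodal
in each compartment with the PFD flipping ~180° between compartments. After
only 60 s, 20 of 100 CONJ cells already express WC-like bimodality within a
compartment; with the full 600 s session that fraction rises to a clear
majority and every HD→CONJ weight column becomes bimodal with modes ~180°
apart:

```r
rep$weight_corr$hd_to_bd
#> [1] 0.9312072 0.9661115 0.9752581 1.0000000 1.0000000
```

— the HD→bidirectional weight matrix correlates with its final state already
at the first quartile checkpoint (development is front-loaded), reaching 1 at
the end of learning, after which the frozen test phase leaves it untouched.

The landmark experiments use the attractor mode:

```r
rd <- run_experiment(experiment_config("landmark_distal", seed = 1))
rp <- run_experiment(experiment_config("landmark_proximal", seed = 1))
compare_landmark_modes(rd, rp)$summary
#>       mode  mean_dev mean_abs_dev
#> 1   distal   6.27698      8.10075
#> 2 proximal -50.42125     50.39711
```

With distal landmarks the ADN PFDs deviate only a few degrees from their
pre-learning arrangement; with the same landmarks at 1/8 of the arena radius
the learned visual loop carries no directional information and the system
drifts several times further. (Both numbers are realisations of a noisy
process; the ordering, not the exact values, is the stable property.)

A thin CLI wraps the same machinery:

```sh
Rscript inst/scripts/run_experiment.R --experiment three_comp --seed 7 --out out/three
```

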