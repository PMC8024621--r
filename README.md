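# kuramotoFC

Frequency-resolved functional connectivity from delay-coupled phase
oscillators on brain connectomes.

## What this package is for

Functional networks measured with high-temporal-resolution imaging (MEG,
EEG) change with the oscillation frequency: region pairs that are strongly
correlated in the theta band can be uncorrelated — or anti-correlated — in
the gamma band. Because both the axonal transmission delay and the
connection strength between two regions grow out of the same anatomical
quantity, their Euclidean distance, their individual contributions to this
frequency dependence are confounded in empirical data. `kuramotoFC` is a
simulation laboratory for separating them, aimed at computational
neuroscientists studying structure–function relationships in whole-brain
network models.

The model is the generalized Kuramoto system with delayed interactions and
phase noise,

    dθ_i/dt = ω_i + ξ_i(t) + (K/N) Σ_j a_ij sin[θ_j(t − τ_ij) − θ_i(t)],

run on a weighted connectome `a_ij` (normalized weights in (0, 1]) with
distance-proportional delays `τ_ij = d_ij / v` (conduction speed `v`,
default 5 m/s). Synchrony between nodes is summarized by the correlation
index

    σ_ij = ⟨ cos(θ_i − θ_j) ⟩   ∈ [−1, 1],

averaged over the recording window and over ensemble realizations. Sweeping
the mean natural frequency across the physiological bands yields the
frequency-resolved functional network, and two laws emerge that the package
quantifies and tests: the *delay* of a connection sets the **rate** at which
σ oscillates with frequency (locking flips near ν ≈ 250/τ Hz, τ in ms),
while its *weight* sets the **amplitude** of those oscillations.

The package provides:

* `connectome()` / `read_connectome()` / `synthetic_connectome()` /
  `pair_connectome()` — validated weight/distance containers, delimited
  text IO, and generators emulating cortical structural statistics
  (hemispheric blocks, modules, five-decade heavy-tailed weights, negative
  weight–distance relation);
* `distance_delays()` / `uniform_delays()` / `binarize()` — delay rules and
  the structural control transformations;
* `simulate_phases()` / `run_ensemble()` — an adaptive Bogacki–Shampine
  3(2) delay-differential-equation integrator (Rcpp) with cubic-Hermite
  history interpolation and Euler–Maruyama phase noise;
* `correlation_index()` / `ensemble_fc()` / `fc_ci()` — functional-network
  estimation with across-realization confidence bands;
* `bin_correlation()`, `fc_similarity()`, `frequency_sweep()`,
  `pair_correlation_curve()`, `two_node_locked_state()` — the analyses:
  weight/distance binning, structure–function similarity distance,
  frequency sweeps, and the analytic two-oscillator locking oracle;
* `experiment_spec()` / `run_experiment()` — reproducible experiment
  drivers with manifests (plus a thin CLI in `inst/scripts/`).

## Worked example

```r
library(kuramotoFC)

con <- synthetic_connectome(n = 20, n_modules = 2, seed = 1)
summary(con)
#> Connectome summary: n = 20, m = 78, density = 41.1%
#>   weight span: 1.42e-05 - 1 (4.85 decades)
#>   edge distances: 8.7 - 129.1 mm
#>   Pearson cor(weight, distance) over edges: -0.095

cfg <- sim_config(mean_freq = 10, t_transient = 7, t_record = 1.2,
                  n_realizations = 10, seed = 1)
sw <- frequency_sweep(con, distance_delays(con, 5), cfg, freqs = c(3, 23, 51))
sw
#> Frequency sweep over 3 mean frequencies (Hz)
#>  freq similarity mean_sigma_connected min_sigma_connected
#>     3    0.09618              0.87626             -0.3251
#>    23    0.05363              0.40250             -0.2803
#>    51    0.03897             -0.01233             -0.8716
#>   similarity minimum at 51 Hz (grid resolution 20)
```

At 3 Hz the network synchronizes and the mean correlation index over
connected pairs is high (0.88); as the mean frequency climbs into the gamma
range the fixed transmission delays translate into ever larger phase lags,
the mean correlation collapses (−0.01 at 51 Hz) and strongly anti-correlated
pairs appear (minimum σ = −0.87). The `similarity` column is the
structure–function distance between σ and the weight matrix over connected
pairs — smaller means more similar.

The analytic oracle explains pair-level locking. At 35 Hz a 10 ms delay
puts an isolated pair in the bistable region between in-phase and
anti-phase locking:

```r
two_node_locked_state(0.25, tau = 10, freq = 35)
#> Two-oscillator locked state at nu = 35 Hz, tau = 10 ms, K = 0.25 rad/ms: bistable
#>      branch     Omega Omega_tau stable
#>    in_phase 0.0662126  0.662126   TRUE
#>    in_phase 0.3877776  3.877776  FALSE
#>    in_phase 0.4698887  4.698887  FALSE
#>  anti_phase 0.2869935  2.869935   TRUE
```

`Omega` is the locked angular frequency in rad/ms; stability follows the
sign of cos(Ωτ) per branch.

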