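---
title: "Methods: frequency-resolved functional connectivity from delay-coupled phase oscillators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: frequency-resolved functional connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Each node of a structural brain network (a *connectome*) is reduced to a
single phase oscillator representing the oscillatory activity of a region of
interest. The phases evolve according to the generalized (delayed, noisy)
Kuramoto model

$$\dot\theta_i(t) \;=\; \omega_i \;+\; \xi_i(t)
  \;+\; \frac{K}{N}\sum_{j=1}^{N} a_{ij}\,
  \sin\!\big[\theta_j(t-\tau_{ij}) - \theta_i(t)\big],$$

where $\omega_i = 2\pi\nu_i$ is the natural angular frequency of node $i$,
$a_{ij} \in (0,1]$ is the normalized structural connection weight (zero in
the absence of a link), $\tau_{ij}$ the transmission delay of that link, and
$\xi_i$ independent Gaussian white noise. Delays are distance-driven:
$\tau_{ij} = d_{ij}/v$ with $d_{ij}$ the Euclidean distance between the
regions and $v$ the conduction speed (default 5 m/s, so a 25 mm link has a
5 ms delay). The synchrony between two nodes is quantified by the
*correlation index*

$$\sigma_{ij} \;=\; \big\langle \cos\big[\theta_i(t) - \theta_j(t)\big]
  \big\rangle \in [-1, 1],$$

which is $1$ for phase-locked in-phase pairs, $-1$ for anti-phase pairs and
$0$ for uncorrelated phases. Scanning the mean natural frequency $\nu_0$
across the physiological bands (theta $\approx$ 3 Hz through high gamma
$\approx$ 51 Hz) yields a *frequency-resolved* family of functional networks
$\sigma(\nu_0)$.

The scientific core is the separation of two influences that are confounded
in real anatomy, where both grow out of distance: the **delay** $\tau_{ij}$
sets the *rate* at which $\sigma_{ij}$ varies with frequency (locking flips
from in-phase to anti-phase near $\nu \approx 250/\tau$ Hz with $\tau$ in
ms), while the **weight** $a_{ij}$ sets the *amplitude* of that variation.

## Units and default parameters

The integrator works on a millisecond time base, and every rate-like
parameter follows it:

| parameter | meaning | unit | default |
|---|---|---|---|
| `mean_freq` | mean natural frequency $\nu_0$ | Hz | per sweep |
| `freq_sd` | SD of the $\nu_i$ distribution | Hz | 0.1 |
| `coupling` | prefactor $K/N$ | rad/ms | 0.25 |
| `noise_sd` | white-noise intensity | rad ms$^{-1/2}$ | 0.05 |
| `t_transient` | discarded transient | s | 7 |
| `t_record` | recording window | s | 12 |
| `record_dt` | sampling/noise step | ms | 1 |
| `n_realizations` | ensemble size | — | 200 |
| speed | conduction speed | m/s (= mm/ms) | 5 |

Distances are in mm and delays in ms; frequencies are quoted in Hz and
converted internally ($\omega = 2\pi\nu/1000$ rad/ms).

The time base of `coupling` and `noise_sd` deserves a comment because
dimensionless-looking values like $K/N = 0.25$ only acquire meaning relative
to a clock. We fixed the millisecond reading after checking both candidates
against the qualitative regime the model must inhabit: with $K/N$ read per
millisecond the weighted 66-node network sits *above* its synchronization
transition at low frequencies — the mean correlation index over connected
pairs is close to 1 at 3 Hz and decays toward zero at 51 Hz as the delays
dephase the network, with anti-correlated pairs appearing from the beta
range on. Read per second, the identical network is deeply subcritical
(mean $\sigma \approx 0.02$ at every band) and no frequency structure
survives, which contradicts the phenomenon the model exists to produce. The
acceptance script recomputes the supercritical signature from scratch.

One consequence matters for controlled two-node experiments: a finite
coupling shifts the locking frequency of an isolated pair by up to
$1000\,K w/(2\pi)$ Hz (from the self-consistency condition below). The
delay-sets-rate check therefore uses a small pair weight ($w = 0.05$, shift
$\approx 2$ Hz, one grid step of the frequency sweep), so that the measured
zero crossings reflect the delay alone. Inside the full network this shift
is irrelevant because pairs are enslaved to the collective rhythm.

## Numerical scheme

The system is a set of stochastic delay differential equations. We advance
the deterministic part with an adaptive embedded Bogacki–Shampine 3(2) pair
(absolute/relative tolerances $10^{-8}$/$10^{-5}$, minimum step 0.001 ms)
between fixed macro-steps of length `record_dt`; after each macro-step one
Gaussian increment of standard deviation `noise_sd` $\times\sqrt{\Delta t}$
is added to every phase (Euler–Maruyama). Splitting the noise from the
high-order deterministic stepper keeps the strong order of the noise-free
dynamics where trajectories are smooth, at the cost of fixing the noise
resolution at `record_dt`; halving `record_dt` is the sensitivity check.

Delayed states $\theta_j(t-\tau_{ij})$ are evaluated by cubic Hermite
interpolation on the dense history of accepted steps (state and derivative
at both ends), which is order-matched to the integrator. Two standard DDE
subtleties are handled conservatively:

* the step size is capped by the smallest positive delay, so a step never
  needs delayed values from inside itself (no waveform iteration);
* the history before $t = 0$ is the constant initial phase,
  $\theta_i(t<0) = \theta_i(0)$. The paper-scale transient of 7 s is three
  orders of magnitude longer than the largest delay ($\le$ 32 mm at
  5 m/s), so the arbitrary history rule cannot influence the recorded
  window.

Initial phases are uniform on $[0, 2\pi)$; phases are stored wrapped to
$(-\pi, \pi]$ (only phase differences enter every analysis, so wrapping is
lossless; `unwrap_phases()` reconstructs continuous phases for
diagnostics). Each ensemble realization redraws initial phases *and*
natural frequencies; per-realization seeds are derived from the
configuration seed by one `sample.int()` call, which makes ensembles
reproducible and order-independent.

Correctness anchors in the test suite: an uncoupled oscillator advances at
exactly $\omega$; with all delays zero the integrator agrees with an
independent fixed-step RK4 classic-Kuramoto reference to better than
$10^{-4}$ rad over 2 s; the phase variance of a noisy uncoupled node grows
linearly with slope `noise_sd`$^2$; and noise-free pair simulations
reproduce the analytic locking diagram (below).

## Averaging and uncertainty

The angle brackets in $\sigma_{ij}$ are read as averaging over **both** time
(within the recording window) and realizations: the time average is taken
per realization, then averaged element-wise across the ensemble
(`ensemble_fc()`). The across-realization SD is retained, and "$p$-value
0.05" bands are computed as 95% $t$-intervals of the ensemble mean
(`fc_ci()`). Binned summaries (`bin_correlation()`) group directly
connected pairs into half-open bins — width 0.05 for weights, 16 mm for
distances, centred on the requested values — and report the bin mean with a
95% $t$-interval across contributing pairs.

The structure–function similarity (`fc_similarity()`) is the Euclidean norm
of $\sigma - W$ over masked upper-triangle pairs divided by the pair count;
it is zero iff the matrices agree on the mask and inherits the metric
properties of the scaled norm (property-tested). The default mask is the
connected pairs, where comparing a correlation with a weight is meaningful;
`pairs = "all"` exists for sensitivity analyses. Similarity curves over
frequency are reported with the grid they were computed on (default 2 Hz
steps); the argmin is only resolved to that grid.

## The two-oscillator oracle

For two identical oscillators coupled symmetrically with strength $Kw$ and
delay $\tau$, locked states $\theta_{1,2} = \Omega t\ (\pm\pi)$ satisfy

$$\Omega = \omega \mp K w \sin(\Omega\tau)$$

(in-phase / anti-phase branch), and the in-phase (anti-phase) state is
stable where $\cos(\Omega\tau) > 0$ ($< 0$). `two_node_locked_state()`
collects *all* self-consistent roots by a sign-change scan over
$[\omega - \frac{3}{2}Kw,\ \omega + \frac{3}{2}Kw]$ refined with
`uniroot()` (tolerance $10^{-12}$), plus a damped fixed-point iteration
from $\Omega_0 = \omega$ for the principal root, and classifies the system
as `in_phase`, `anti_phase`, `bistable` or `drift`. In the weak-coupling
limit the boundaries sit at $\nu = (2k+1)\,250/\tau$ Hz, which is the
origin of the delay-sets-rate law. The oracle is used as an independent
check of the simulator on a $10\times10$ $(\nu, \tau)$ grid, excluding a
$\pm2$ Hz band around classification boundaries where critical slowing
makes finite-time simulations undecided.

## The synthetic connectome generator

No connectome matrices are redistributed with the package; instead
`synthetic_connectome()` generates networks that emulate the gross
statistics of cortical weight/distance matrices, and those statistics are
what the study conditions require:

* two hemispheric blocks of nodes in 3D (80 × 100 × 80 mm boxes), overall
  diameter rescaled to at most 160 mm;
* a modular topology (default 6 modules; edge probabilities 0.7 within a
  module, 0.25 between modules of a hemisphere, 0.08 across hemispheres,
  giving a density near 25%), with disconnected components joined through
  their closest node pair;
* edge weights drawn log-uniformly over 5 decades, damped by
  $e^{-d/40\,\mathrm{mm}}$, renormalized to maximum 1, and truncated at the
  absence threshold $10^{-5}$ — producing a heavy-tailed weight
  distribution spanning $\ge$ 4 decades and a negative weight–distance
  correlation with strong links concentrated at short range.

What the generator does **not** emulate: the true tractography topology
(hubs, rich club, homotopic inter-hemispheric links), the empirical
log-normal shape of the weight histogram, or any subject-level variability.
Tests that pass on these networks therefore validate the *mechanisms* —
delay-set rate, weight-set amplitude, frequency-resolved decorrelation —
not quantitative agreement with any specific empirical connectome; analyses
of real data should load the corresponding matrices with
`read_connectome()`.

`pair_connectome()` builds block-diagonal collections of isolated two-node
systems for the controlled experiments in which every pair's weight and
delay are known exactly.

## Control experiments

Two controls separate the delay and weight pathways end-to-end
(`run_experiment()` with `binarize = TRUE` or `fixed_delay`):

* **Binary network** — all weights set to 1, delays still
  distance-proportional: distance-binned $\sigma(\nu)$ curves separate by
  their rate (first zero crossing decreasing with distance). This control
  is run on isolated unit-weight pairs at 50/75/100 mm with a weak coupling
  ($K\tau < 1$), for two reasons. In a *dense* binary network the summed
  input ($\approx$ degree $\times K/N$) dwarfs $\omega$ and the network
  locks rigidly with $\sigma \approx 1$ at every band — a real regime of
  the model, but one in which the distance effect is invisible. And for
  strongly coupled pairs ($K\tau > 1$) wide bistable zones appear in which
  the ensemble mean of $\sigma$ measures basin sizes rather than a locked
  state, which makes zero-crossing estimates binomially noisy at desk-scale
  ensembles; $K\tau < 1$ leaves a single locked branch and sharp,
  reproducible transitions.
* **Fixed delay** — all delays 10 ms, weights retained: weight-binned
  curves share one rate (zero crossings within a grid step) but their
  peak-to-trough amplitude grows with the bin weight. This control runs on
  a 40-node synthetic network, whose 0.15 and 0.25 weight bins are
  populated.

## Problem sizes and determinism

Paper scale is 200 realizations × 12 s recording after a 7 s transient.
The bundled analyses use deliberately smaller designs chosen to make every
claim measurable on a single workstation: ensembles of 10–20 realizations
with 1.2–3 s recordings for the network sweeps, 10 realizations for the
controlled pair curves, and full 12 s single runs for the noise-free
locking grid. `experiment_spec(scale = )` rescales the ensemble size and
recording window proportionally, so paper scale is one argument away.
Every random draw — connectome generation, initial phases, frequency
draws, noise — descends from explicit integer seeds, and re-running any
experiment specification reproduces its outputs bitwise (tested on file
hashes).

## Known limitations

* Phase oscillators carry no amplitude dynamics; BOLD/MEG forward models
  and neural-mass dynamics are out of scope.
* The noise enters at the fixed macro-step, not inside the adaptive
  stepper; very strong noise together with a coarse `record_dt` would
  degrade the effective integration order.
* $\sigma_{ij}$ is a zero-lag synchrony measure; lagged or spectral
  functional-connectivity estimators (PLV, coherence, phase-lag index) are
  intentionally not provided.
* The similarity argmin is grid-limited, and on synthetic connectomes its
  location depends on the generated weight/distance statistics; comparing
  it with empirical band assignments requires the corresponding real
  matrices.
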