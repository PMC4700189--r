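---
title: "Innate attractor networks from molecular markers: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Innate attractor networks from molecular markers: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmbann)
```

## The model

`mmbann` simulates attractor neural networks whose recurrent connections
are *innate*: they are wired once, at construction time, from a metric on
model "molecular markers" distributed over the neurons, rather than
learned from activity.  Two marker geometries give two families of
attractors.

**Isolated point attractors (d = 0).**  `M` marker classes with `L`
interchangeable instances each are spread over `N` neurons so that every
class occupies `L` distinct neurons, no neuron repeats a class, and
per-neuron loads are as even as possible (`q = M L / N`, fractional `q`
supported).  Neurons sharing a class are coupled `+1`
(`connect_point_attractor()`).  Each class's `L` neurons then form an
isolated fixed point of the dynamics; for small `L / N`, distinct class
states sit at Hamming distance near `2L` from each other.

**Ring (bump) attractors (d = 1).**  `M = k N` markers are ordered on a
ring with distance `min(|i - j|, M - |i - j|)`.  Each neuron owns `k`
markers, pairwise more than `Delta` apart, so one neuron never bridges
nearby ring positions.  Neurons holding markers closer than `delta` are
coupled `+1`, all other pairs `-sigma`
(`connect_ring_attractor()`).  The owners of any `L` consecutive markers
— a *candidate state* (`candidate_state_set()`) — form a bump: a stable
state in which `L` neurons are active and the rest are inhibited.
Adjacent candidate states share all but one neuron (Hamming distance 2),
so the `M` candidates form a closed one-dimensional chain: the network
has about `k N` attractor states, more than it has neurons.

The ring size is `M`, not `N`: the markers, not the neurons, carry the
circular metric.  With `k > 1` a neuron appears at `k` well-separated
ring positions, which is what lets the state count exceed `N` — and what
creates weight disorder, because two neurons' *other* markers can land
within `delta` of each other by chance, converting a `-sigma` pair into
a `+1` pair.  At `delta = 12`, `M = 900`, `k = 3` about a fifth of all
pairs are excitatory for this reason.  This disorder drives most of the
phenomenology below.

## Dynamics

States are binary vectors of length `N`.  The asynchronous rule updates
one uniformly random neuron at a time, `v_i <- 1` iff
`sum_j T_ij v_j > theta_i`, with one sweep defined as `N` micro-updates
(`async_relax()`).  For symmetric zero-diagonal weights the energy
`-v'Tv/2 + theta'v` (`hopfield_energy()`) never increases, so
relaxation terminates in a fixed point, typically within a few sweeps.
`enumerate_stable_states()` provides the exhaustive ground truth for
networks up to `N = 20` and is used throughout the tests.

**Threshold accommodation.**  To visit the whole chain of attractor
states, each neuron's threshold tracks its own recent activity:

```
theta_i(t) = theta0 + dtheta * (# sweeps active among the last tau sweeps)
```

a sliding-window integral of activity with increment `dtheta` (default
0.1 per sweep) and window `tau` (default 200 sweeps).  Active neurons
fatigue; the bump's trailing edge drops out, a fresh neuron joins at the
front, and the state slides along the chain indefinitely
(`run_accommodation_dynamics()`).

Two update schemes are provided.  The default, `"rank"`, is
winner-take-L: per sweep the `L` neurons with the largest
fatigue-corrected input `h_i - theta_i` are active — the same
fixed-activity rule the point-attractor experiments use in their
relaxation phase.  The alternative `"async"` applies the asynchronous
rule above.  We ship both because the choice matters on disordered
rings: with `k >= 2` the weight spectrum is quantized in steps of
`1 + sigma`, and under purely local asynchronous updates the chance
`+1` couplings pin the bump (it freezes for tens of sweeps, diffuses,
and reverses direction), whereas the rank competition lets a fatigued
trailing neuron lose its slot to the freshest forward neighbour and the
traversal becomes ballistic: a clean, near-periodic circulation over all
`k N` states.  The exponential-decay threshold law was also tried and
behaves strictly worse than the sliding window (the fatigue trail decays
during pinning episodes and the drift direction is forgotten).

The activity level `L` of the rank scheme is never assumed: it is
measured per network as the median active count of static relaxations
from random states (`measure_bump_width()`), i.e. the bump width the
network itself selects (about `delta + 3` at `sigma = 3`).

**Traversal statistics.**  The analysis surface is the Hamming distance
between states at different times: the L-plot (`lplot()`) resolves it by
`(t, dt)`, the mean distance curve (`mean_distance_curve()`, computed
via per-neuron FFT autocorrelations) averages over `t`.  On a smoothly
traversed ring the curve rises linearly at 2 bits per state passed,
saturates near `2 L`, dips to a plateau `D` once about `Delta` states
have been passed (the reference neurons' other markers begin to fall
under the displaced bump; theory
`D = 2L (1 - (k - 1) L / M)`, `theoretical_plateau_distance()`), and
returns near zero after one full period `T_net`.  Hence
`T_net * slope = 2 M` and the state count `M' = T_net * slope / 2`
(`estimate_period()`, `estimate_slope()`, `estimate_state_count()`,
`plateau_distance()`).

A caveat we state plainly: the absolute traversal *speed* of the
reconstruction is about 0.2 states per sweep on the `N = 300`, `M = 900`
reference network, so the raw period comes out near 4000 sweeps.  The
speed is set by the ratio of the fatigue increment to the local weight
margins, and the disorder described above holds the effective margin
near 6-7 units; the unit-free relations (`T_net * slope = 2M`, `M'`,
`D`, the mean activity near 15) are insensitive to it, but the raw
period in sweeps is a property of the reconstructed accommodation law,
not a robust observable of the construction.

Not every marker realization circulates: roughly a third of `k = 3`
draws contain a disorder defect strong enough to reflect the bump,
which then bounces inside a segment instead of traversing — and the
traversal statistics are undefined.  `traverses_full_ring()` gates on
this qualitative regime (the smooth drift must span the whole ring),
and `ring_traversal_experiment()` redraws the marker realization, with
seeds derived deterministically from the run's seed, until a
circulating run is obtained (the number discarded is reported).
Injecting score noise to shake the bump past such defects was tried
and rejected: it does not free the trapped runs and it blurs the
periodicity of the clean ones.

**Critical marker load.**  As `k` grows, the excitatory disorder
thickens until smooth traversal breaks: the activity leaps between
distant attractor states, each leap reversing the drift direction
(`detect_jumps()`).  `empirical_kc()` scans `k`, calling a run smooth
when the drift spans the full ring with zero leaps, and reports the
largest majority-smooth `k`.  On `N = 300`, `Delta = 80`, `delta = 12`,
`sigma = 3` networks the boundary sits at `k_c = 5` under this
package's dynamics (jump counts per run: ~0-4 at `k = 5`, ~10-20 at
`k = 6`, tens at `k = 7`, hundreds at `k = 8`); the load-based theory
`k_c = N / (2 delta c)`, `c` in [1, 2] (`critical_k_formula()`),
brackets the range 6.25-12.5.

## Spiking implementation

`simulate_lif()` re-implements the ring attractor with leaky
integrate-and-fire neurons: Euler integration of
`dv/dt = (-(v - v_rest)(1 + g_ahp * Ca) + I_exc - w_inh * p) / tau_m`,
spike-and-reset at `v_thresh`, per-spike calcium increments decaying
with `tau_ca = 0.1` s, a lumped inhibitory pool `p` fed by every
excitatory spike, and optional Gaussian membrane noise.  The
calcium-gated leak is the spiking counterpart of threshold
accommodation: it fatigues recently active neurons and makes the bump
of spiking activity slide over the ring, which the standard-neuron-set
raster (`sns_projection()`: summed membrane potentials of the neurons
owning markers in a window of width `L + 1` around each ring position)
renders as a drifting diagonal band.  Only `tau_ca` and the network
sizes have canonical values; all other constants are this package's
choices, calibrated once so that the `N = 600`, `M = 1200`, `L = 30`
configuration sustains a localized sliding bump
(`tau_m` 20 ms, thresholds -70/-54/-60 mV, `w_exc` 5 mV, `w_inh` 1,
`g_ahp` 3, `delta_ca` 0.05, dt 0.1 ms), and documented as such.  A
brief 50-ms current injection into the seed neurons nucleates the bump;
a single synchronized volley cannot.  With asymmetric wiring
(excitation only from higher to lower marker order, window `L/2`, and
`w_exc` 12 / `w_inh` 0.6 to compensate the halved in-degree) the bump
becomes a unidirectional travelling wave whose front edge is visibly
sharper than its tail.

## Readout learning (d = 0)

The perceptron experiment couples `R = 100` input fibres to the
`N = 300` point-attractor network through a weight matrix `W`.  Each
trial has two phases: the `L` most-driven neurons are excited
(`initial_state_top_l()`), then the network relaxes at fixed activity
(`relax_winner_take_l()`, a greedy exchange of the weakest active
neuron for the strongest inactive one — monotone in the set energy, so
it cannot oscillate).  `select_input_vectors()` draws random inputs in
`[-1, 1]^R` until every one of `M = 100` distinct attractors is
occupied.  The modified perceptron rule
(`train_modified_perceptron()`) adds `X` to the columns of neurons that
should be active but are not, and subtracts it from the converse — a
per-neuron Rosenblatt rule whose targets are the attractor states fixed
at selection time.  Fixing the targets is a deliberate choice: letting
phase 2 re-relax during learning lets the huge early weight updates
(`|X|^2 ~ R/3` against initial drives well below 1) scramble the
input-to-attractor map, and the stored patterns collapse onto a handful
of attractors.  With fixed targets the procedure converges in ~10-15
passes and reproduces every assignment exactly.

Noise robustness (`noise_response_error()`) perturbs each coordinate by
uniform noise of amplitude `eta` and scores the normalized Hamming
distance (mismatched bits over `2L`) between the reached state and the
assigned one; the all-or-nothing misclassification rate is available as
an option.  The attractor network's basins absorb the noise (mean error
stays below 0.05 beyond `eta = 0.5`); the unconnected baseline — same
readout, no relaxation, scored against its own noiseless top-`L`
responses, and provably unchanged by training since its initial and
final states always coincide — degrades an order of magnitude faster.

## Self-organizing mapping (d = 1)

`train_som()` couples `R` broadly tuned circular-Gaussian receptors
reading a cyclic stimulus `phi` to a `k = 1` ring attractor.  Each step:
activate receptors; excite the `L` most-driven neurons after one relay
of the drive through the recurrent excitation (a bump-matched filter);
relax with receptors off (stable within 3-6 sweeps in over 99% of
steps); then pull active neurons' weight columns towards `X` with rate
`eta`, weighting each column by the neuron's time-averaged activity
over a further 20 sweeps of accommodation drift, so a bump trains
itself together with its immediate neighbours on the attractor chain —
the attractor supplies the Kohonen neighbourhood.  The printed form of
the learning rule (`W <- W + eta (X V' - W)`) is available as
`update = "full"`, but its uniform decay of silent columns collapses
the map onto one attractor, so the default is the masked
per-active-column reading, which matches the rule's verbal description
("the active rows are turned towards the input").

Receptor tuning defaults to width 0.1 of the circle and is annealed
from 0.25 down to the final width during training (coarse-to-fine, the
package's counterpart of Kohonen's shrinking neighbourhood; with the
naive width `3/R = 0.01` the inputs are pairwise orthogonal and no
continuous map can form).  After 20000 steps the learned map is locally
continuous — consecutive stimuli activate adjacent attractor states in
over 95% of steps, and the converged states cover most of the ring —
but global fold defects survive in most runs: the circular association
between `phi` and ring position comes out between roughly 0.3 and 0.75
depending on the realization, and does not improve with training
length, learning-rate schedules, or the neighbourhood variants we
tried (annealed initial activation, slide-arc and diffusion
neighbourhoods).  With a fixed, bump-sized output
neighbourhood on a ring, defect pairs are metastable; we report the
maps as learned rather than selecting fold-free realizations.

In the two-ring experiment (`two_ring_som_experiment()`) the same
population carries two independent full ring attractors (one marker
from each of two rings per neuron, union excitation rule, strong
inhibition).  Training recruits exactly one ring: the map is far more
continuous in the winning ring's enumeration than in the other's, and
which ring wins depends on the initial conditions.

## Dimensionality

`dimension_bound()` evaluates the packing bound for d-dimensional
attractor grids: representing `l` grid elements per dimension as bump
states requires `l^d <= N^2 / L`, i.e.
`d <= log(N^2 / L) / log(l)` (7 for `N = 1e4`, `l = L = 10`; 3 for
`l = L = 100`), with the companion connection-load check
`(2 delta)^d k < N`.

## Reproducibility, sizes, and limits

Every stochastic entry point takes a `seed` and scopes R's RNG to the
call; the rank dynamics is deterministic given the network, so
replicate variability is carried by the network construction seed.  The
reference problem sizes used throughout the package's own experiments
are the published ones (`N = 300` rings with `M` up to 2400, 16000-sweep
traversal runs covering 3+ periods, `R = N = 300` SOMs trained for
20000 steps, `N = 600` LIF networks integrated at 0.1 ms for a few
seconds); all complete in seconds to a few minutes on one core, the
heavy loops being compiled.  Serialization is plain text (TSV + JSON)
via `write_network()` / `write_trajectory()`.

What the synthetic experiments do *not* emulate: real marker chemistry
(classes are abstract labels; the ring metric is exact, not a noisy
affinity), neuron heterogeneity, conduction delays, and any learning of
the recurrent weights themselves.  Conclusions about robustness
therefore concern the idealized wiring rule, and the two quantities we
flag as reconstruction-dependent — the raw traversal period and the
exact critical load — should be read as properties of this package's
dynamics, not of the construction as such.
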