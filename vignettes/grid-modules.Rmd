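---
title: "Self-organization of grid modules in coupled attractor networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-organization of grid modules in coupled attractor networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

Grid cells in the medial entorhinal cortex (MEC) fire on a triangular
lattice of locations, and are organized into discrete *modules*: groups of
cells sharing one spatial period (scale) and one lattice orientation, with
scale ratios between successive modules clustering in the range 1.4--1.7.
`gridmodules` simulates a mechanism by which this discreteness
self-organizes from smooth anatomical gradients.

The model is a stack of `h` two-dimensional continuous attractor networks
(the classic recurrent-inhibition grid architecture), indexed `z = 1`
(dorsal) to `z = h` (ventral). Each network is an `n x n` sheet of
rate-based neurons. Three ingredients per sheet:

* **Broad drive.** Every neuron receives feedforward excitation
  `a(r) = a_mag exp(-a_fall r_scaled^2)` for `r_scaled < 1` (else 0), where
  `r_scaled` is the distance from the sheet center divided by `n`. The taper
  toward the edges prevents boundary artifacts in the pattern.
* **Center-surround inhibition.** Each neuron inhibits neighbors in its own
  sheet with the radial weight
  `w(r; z) = -(w_mag / l(z)^2) (1 - cos(pi r / l(z))) / 2` for `r < 2 l(z)`,
  strongest at the *inhibition distance* `l(z)`. The `1/l^2` scaling keeps
  integrated inhibition depth-independent (the kernels in `build_kernels()`
  satisfy this to under 5%). Competition between broad drive and surround
  inhibition makes the population activity crystallize into a triangular
  lattice of activity bumps with period `lambda(z) ~ 2.2 l(z)` (the
  proportionality is the uncoupled-stack invariant checked in the tests).
* **Velocity-modulated subpopulations.** Neurons belong to four
  subpopulations tiling the sheet in 2x2 blocks, each with a preferred
  network direction (its inhibitory outputs are shifted by `xi` neurons) and
  a paired spatial direction (its drive is multiplied by
  `1 + alpha E . V`). This makes the whole pattern translate in proportion
  to the animal's displacement (path integration), projecting the network
  lattice onto single-neuron spatial rate maps with spatial scale
  `Lambda = lambda / gain`, where the gain is proportional to the velocity
  gain `alpha` (`measure_path_integration()` measures this directly;
  doubling `alpha` halves `Lambda`).

The inhibition distance increases smoothly along the stack,

```
l(z) = [l_min^l_exp + (l_max^l_exp - l_min^l_exp) (z - 1)/(h - 1)]^(1/l_exp),
```

with the log-linear limit at `l_exp = 0`; more negative `l_exp` is more
concave. Alone, this yields a smooth gradient of grid scales -- no modules.

The new ingredient is **excitatory coupling between neighboring sheets**:
each neuron in network `z` excites neurons near the same sheet position in
network `z - 1` with the radial weight
`u(r) = (u_mag / d^2)(1 + cos(pi r / d)) / 2` for `r < d`. Coupling makes
corresponding activity peaks in adjacent sheets attract, adding rigidity
that opposes the changing inhibition distance. The compromise is geometric:
runs of adjacent networks share one lattice (a module), and at module
interfaces the two lattices adopt a registered, *commensurate* relationship
-- principally scale ratio sqrt(3) with a 30 degree orientation difference
-- because registered lattices maximize peak overlap. Weaker or broader
coupling instead yields *discommensurate* relationships (registered patches
separated by a mesh of discommensurations; ratios 1.1--1.4, differences
0--10 degrees), *incommensurate* lattices (no registry, weak coupling), or
occasional *defects* (low overlap under strong coupling, ratio < 1.1 with
difference > 10 degrees). `classify_relationship()` implements exactly this
taxonomy.

## Dynamics and numerics

The update is the explicit rectified Euler scheme, exactly as the model is
defined -- the discrete-time equation *is* the integrator:

```
tau (s(t + dt) - s(t))/dt + s(t) = {recurrent + coupling + drive}_+
```

with `{.}_+ = max(., 0)` applied to the summed input. Because
`s(t + dt) = (1 - dt/tau) s(t) + (dt/tau) {input}_+`, rates remain
nonnegative whenever `dt <= tau` (enforced at construction; `dt = 1` ms,
`tau = 10` ms by default). Sheets are open (non-periodic): kernel mass
falling off-sheet is dropped, with no renormalization -- the tapered drive
handles the boundary.

The recurrent and coupling sums are linear convolutions with compactly
supported kernels, evaluated by zero-padded FFTs (FFTW). The subpopulation
output shift and the coupling-shift jitter are applied to the *source*
field before the transform, so each sheet needs one packed complex FFT per
step plus half an inverse; a 12-network standard stack steps in a few
milliseconds. The padded size is the next 5-smooth integer that fits sheet
plus kernel support, so circular wraparound can never reach the read
window; the optimized path agrees with direct summation to 1e-9 and a
single step matches a hand-composed update to machine precision (tested).

Initialization draws rates independently and uniformly from `[0, 1)`; a
settling period with the animal at rest then relaxes the sheet into its
lattice (clean patterns appear within ~2 s of simulated time; protocols
here settle for 20 s). All randomness -- initial rates, trajectories,
recorded-neuron choices, noise, spiking, coupling jitter -- flows from one
replicate seed, so every run replays bit-identically.

### Variant switches

`sim_flags()` and `run_variant()` expose the perturbation variants:

* `rate_noise`: independent zero-mean Gaussian noise per neuron per step,
  re-rectified. The source description leaves the magnitude unspecified;
  the package default is **sd 0.02**, about 5% of a typical activity-peak
  rate (peak rates in the standard configuration are ~0.4--0.7). This is a
  package choice, stated here prominently.
* `spiking`: each neuron emits Poisson spikes with intensity
  `rate x spike_rate_scale` (default **500 spikes/s per unit rate**, also a
  package choice); normalized spike counts, not rates, propagate through
  the recurrent and coupling sums, and recorded neurons report counts.
* `coupling_shift`: each neuron's coupling outputs are displaced by a fixed
  random shift of one neuron in both x and y, drawn once per run.
* `concave_less` / `concave_more`: `l_exp` -0.5 / -2 (defaults -1).
* `reverse_coupling`, `bidirectional`, `d_equals_l`, `small_system`
  (`h = 6`, `n = 76`): as named.

## Trajectories

The model's claims concern pattern geometry, not behavior, so the animal
trajectory only needs to be a smooth, space-filling walk with realistic
speeds. `generate_trajectory()` evolves turning rate and speed as
mean-reverting (Ornstein-Uhlenbeck) processes on a 10 ms control grid
(speed mean 0.35 m/s, sd 0.15, relaxation 1 s; turning sd 3 rad/s,
relaxation 0.3 s -- all configurable), clips speed to `[0, speed_max]`,
deflects the heading inward at the wall of the circular enclosure (180 cm
diameter default), and interpolates to the 1 ms simulation step. Over 500 s
it covers over 90% of the 5 cm bins of the arena (tested), and its speed
statistics are stationary. What it does not emulate: thigmotaxis, rest
bouts, home-base behavior -- so passing tests say nothing about
trajectory-statistics-sensitive analyses on real data.
`load_trajectory()` accepts user-supplied `time x y` columnar text instead.

## The analysis chain

Rate maps (`build_rate_map()`) bin recorded activity by position (3 cm bins
and Gaussian smoothing of 1 bin sd by default -- conventional choices, as
the source leaves binning unstated), averaging rates per bin
(occupancy-normalized counts in spiking mode) with NA-aware smoothing.

`autocorrelogram()` computes the Pearson correlation of a map with itself
at every displacement over the overlapping defined bins. `grid_props()`
then scores it:

* The angle-averaged autocorrelation as a function of radius bounds an
  annulus: inner radius at its first local minimum, outer at 1.5x the
  six-peak ring radius (the angle-averaged maximum, iterated once). Radii
  whose circles have under half their angular samples defined are excluded
  -- a ring holding six peaks must lie mostly inside the map.
* **Scale** is the angle-averaged maximum radius (parabolically refined).
  On idealized three-cosine fields this estimator sits at the first
  maximum of the Bessel function J0, 3.3% below the lattice constant (an
  analytic property, used as the test oracle); on bump-like fields -- real
  patterns -- it recovers the lattice constant within one bin.
* **Orientation and gridness** come from the sixth Fourier harmonic of the
  annulus averaged over radius as a function of angle: gridness is the
  sixth-harmonic power divided by total non-constant power (the constant
  angular component is excluded -- a convention this package fixes, since
  the source leaves it open), and orientation is the coefficient's phase
  divided by six, in `[0, 60)` degrees. Fields with gridness >= 0.6 count
  as grids.

`cluster_modules()` groups grid cells into modules by k-means on
standardized (log scale, orientation-on-a-60-degree-circle) coordinates,
with k the number of modes of a Gaussian kernel density over log scale
(Sheather-Jones plug-in bandwidth with a floor of 0.05 log units -- about a
5% scale spread -- so that measurement noise inside a tight module is never
resolved as extra modes; modes below 5% of the density maximum are
ignored). Initial centers come from an ordered split of the scales, making
the procedure deterministic. Adjacent-module scale ratios (larger over
smaller) and orientation differences folded to `[0, 30]` degrees by
sixfold lattice symmetry follow.

`overlay_registry()` extracts activity peaks from two population patterns
and reports the fraction of each pattern's peaks within a capture radius
(30% of the finer pattern's spacing by default) of the other's --
commensurate overlays score 1 for the coarse pattern, random overlays score
the areal coverage of the capture disks. `classify_relationship()` uses the
measured ratio, difference and registry with the taxonomy above; the
commensurate catalogue ships `sqrt(3)/30`, `2/0`, `sqrt(7)/19.1` and
`sqrt(13)/13.9` degrees (the standard triangular coincidence relations; a
package-supplied list, configurable) with matching tolerance 0.05 in ratio
and 3 degrees in angle.

## Protocols and problem sizes

The full-scale standard system (`h = 12`, `n = 160`, 500 s of trajectory,
10 replicates) is what `run_standard()` expresses with its defaults, but it
costs hours per replicate on one CPU. The package's own test and
reproduction protocols therefore run documented reduced configurations,
chosen once:

* **Module geometry** (and the shipped reproduction script): the reduced
  coupled stack `h = 6`, `n = 76` -- the published small-system variant --
  settled 20 s, five replicates, analyzed at the population level.
  It yields three modules whose adjacent-pair geometry is the commensurate
  `sqrt(3) / 30 degrees` relationship.
* **Uncoupled proportionality**: `h = 4` spanning the full `l` range on
  120^2 sheets; measured `lambda(z)/l(z)` is flat to ~1% (the full 12 x
  160^2 stack gives 0.5%).
* **Lesion**: `h = 6`, `n = 76`, full inactivation of the middle network
  after 20 s, 15 s of relaxation. Networks ventral to the lesion are
  untouched (scale within 5%, orientation within 3 degrees); the networks
  dorsal to it relax to a shared, changed pattern.
* **Discommensurate regime and mixed-parameter ensembles**
  (`run_discommensurate()`, `run_ensemble()`): the genuine operating point
  is `n = 230` sheets run for hundreds of seconds across many replicates,
  which is out of reach at desk scale; probes at `n` up to 160 form the
  ventral module but leave the dorsal half smoothly graded. These
  protocols are implemented and structurally tested at small scale, and
  their full-scale statistics are not asserted by the default suite (one
  acceptance check runs a labelled 96^2 probe against the full-scale
  numbers and is expected to fail until run at scale).

Within modules, orientations agree to well under a degree (co-modularity);
between modules scales jump by over 30%. On square open sheets settled at
rest, absolute pattern orientations are partially pinned near the sheet
axes, so across-replicate orientation statistics are reported as dispersion
rather than uniformity.

## Worked example

```{r}
library(gridmodules)
library(ggplot2)

p <- grid_params(h = 6, n = 76)          # reduced coupled stack
rs <- run_standard(coupled = TRUE, params = p, seeds = 1:2, settle = 20,
                   keep_snapshots = TRUE)
glance(rs)
tidy(rs, "pairs")
plot_scale_profile(rs)
plot_overlay(rs$snapshots[[1]][[2]], rs$snapshots[[1]][[3]])
autoplot(rs$partitions[[1]])
```

## Known limitations

* Rate-based neurons with a single relaxation time; no conductances,
  delays, or synaptic plasticity.
* Homogeneous parameters within a sheet apart from the four-way
  subpopulation identity.
* The reduced protocols above stand in for full-scale runs; quantities
  that demand `n = 230` sheets or hundreds of simulated seconds (the
  discommensurate-regime statistics, ensemble scale-ratio distributions)
  are implemented but not reproduced by the default suite.
* The spatial arrangement of the four subpopulations ("evenly tile") is
  fixed here as repeated 2x2 blocks; any even tiling is admissible, and
  none of the measured quantities depend on the choice at the scales
  tested.
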