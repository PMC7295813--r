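---
title: "The tug-of-war model of cluster positioning in cell-sized droplets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The tug-of-war model of cluster positioning in cell-sized droplets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actotug)
library(dplyr)
```

## The system and the model

When cytoplasmic extract is encapsulated in a water-in-oil droplet, the
initial contraction of the actomyosin network collects organelles into a
single nucleus-like body — the *cluster* — and the network then settles into
periodic, ring-shaped contraction waves that are born at the droplet
boundary and travel inward. The cluster's stable position depends sharply on
droplet size: in large droplets it sits at the geometric centre, in small
droplets at the boundary. `actotug` implements a quantitative model of this
two-state positioning together with the measurement pipeline that produces
its inputs.

Two antagonistic processes compete:

* **Centering.** Every wave period $T(D)$ an inward contraction front sweeps
  the droplet and pushes the cluster toward the centre.
* **Edge pulling.** The bulk network between the cluster and the boundary
  can *percolate*: when all crosslinking sites along the gap are
  simultaneously occupied by crosslinkers, a contractile bridge forms and
  pulls the cluster outward.

Crosslinker binding and unbinding are taken to be in equilibrium, so each
site is occupied with probability $1/2$ at every turnover step
$\tau = 1/(k_\mathrm{off} + C_0 k_\mathrm{on})$. With $N$ sites spanning the
gap, a bridge forms in one step with probability $(1/2)^N$, and within a
window $T$,

$$p = 1 - \left[1 - (1/2)^N\right]^{T/\tau}.$$

The number of sites is set by the filament length $L$: a centre-positioned
cluster faces a gap of one radius, $N \simeq R/L = D/(2L)$. Substituting the
empirically affine wave period $T(D)$ gives the edge-positioning probability
as a function of droplet diameter,

$$p(D) = 1 - \left[1 - (1/2)^{D/(2L)}\right]^{T(D)/\tau},$$

a sharply decreasing sigmoid whose $p = 0.5$ crossing defines the transition
diameter $D_c$. Because the mean bridge maturation time is
$\tau_p = 2^N \tau$ (a geometric waiting time), equating $\tau_p = T$ yields
the closed-form estimate $D_c = 2L\,\log_2(T/\tau)$: the transition moves
right with filament length and with crosslinker concentration (through
$\tau$), which is exactly what the condition presets encode.

The closed forms use the *continuous* exponent $D/(2L)$, reproducing the
fitted curves exactly; the stochastic simulator uses the integer site count
`max(1, round(gap/L))`, keeping the discrete process physical. This split is
deliberate and both conventions are exercised against each other in the
test-suite.

## Parameters that matter

| Parameter | Units | Default (control) | Meaning |
|---|---|---|---|
| `L` | μm | 6.1 | filament (contour) length; sets the crosslinking-site spacing |
| `tau` | s | 0.46 | crosslinker turnover time; one occupancy resampling per `tau` |
| `a_T`, `b_T` | s/μm, s | 2.5e-2, 39 | wave period line $T(D) = a_T D + b_T$ |
| `a_v`, `b_v` | 1/s, μm/s | 1.6e-2, −1.3 | wave velocity line $v(D) = a_v D + b_v$ |
| `v_min` | μm/s | 0.05 | velocity floor (see below) |
| `cluster_slope` | — | 0.25 | cluster-to-droplet diameter ratio |
| `T0` | s | 1800 | simulated duration per droplet |
| `dt` | s | `tau` | simulation step: one percolation attempt per turnover time |

Presets for the four experimental conditions (control, α-actinin addition,
gelsolin addition, mDia2 addition) ship as a plain table
(`condition_presets()`); each carries its own wave-period line, and the
transition diameters are always computed with the condition-specific
$T(D)$ — fitting and root finding never share a common period line across
conditions.

**Velocity floor.** The fitted velocity line crosses zero near
$D \approx 81$ μm although waves are observed in droplets down to 16 μm, so
evaluated front speeds are clamped below at `v_min` (default 0.05 μm/s).
This is a deliberate deviation from the raw fit; it only matters below the
zero crossing.

## The stochastic simulator

The event rules of `simulate_cluster()` are this package's reconstruction of
the coupled wave–percolation dynamics; the published description fixes the
ingredients (transport to the centre by waves each period, stochastic bridge
formation between waves, outward transport halted by wave collision) but not
the event scheme, so the scheme here was chosen to be the simplest one that
is faithful to those sentences and validates against the closed form:

1. A front is born at the boundary every period $T(D)$ and travels inward at
   $v(D)$. A front dies when it reaches the centre **or when the next front
   is born** — ring assembly consumes the bulk network, so one front is
   active at a time. (With immortal fronts, droplets whose crossing time
   $R/v$ exceeds $T$ would accumulate a traffic jam of fronts that no
   parameter set can escape.)
2. While the cluster is free, one percolation attempt is made per turnover
   step across the *current* gap, with success probability $(1/2)^N$,
   $N = \mathrm{site\_count}(R - d, L)$; at most one bridge forms per
   period.
3. A bridge pulls the cluster outward at the transport speed (default
   $v(D)$ — the only contraction speed the data quantify; configurable via
   `v_transport`).
4. A front reaching an outward-moving, bridged cluster **stops** the
   outward movement: the contracting ring fuses with the cluster, consuming
   front and bridge. The alternative rule — every collision carries the
   cluster back to the centre — was evaluated and rejected: it prevents any
   parameter set from producing time-averaged DC-ratios above 0.8 at
   intermediate droplet sizes, contradicting both the closed form and the
   observed two-state scatter.
5. A front reaching a *free* cluster captures it and carries it inward
   until the front dies.
6. The cluster is a point by default (its centroid can reach the boundary);
   `cluster_radius_um` activates the finite-size variant, which shortens
   the percolation gap and confines the centroid to $d \le R - r$.

Each run reports $d(t)$ on the `dt` grid; `time_averaged_dc()` computes
$(1/T_0)\int_0^{T_0} d(t)/R\,\mathrm{d}t$ and `classify_position()` applies
the thresholds (simulation scheme: edge above 0.8, centre below 0.2 — point
clusters can touch the boundary, hence the stricter edge cut than the
experimental 0.5; values exactly on a threshold are deliberately
`intermediate` so ties are deterministic).

Validation against the closed form, recomputed by the test-suite: with
control parameters the simulated edge fraction over 200 seeds is
$\ge 0.8$ at $D = 0.5\,D_c$ and $\le 0.2$ at $2\,D_c$, and the fraction
rises monotonically with $L$ and with crosslinker concentration at fixed
diameter.

```{r simulate}
w <- condition_waves("control")
traj <- simulate_cluster(50, L = 6.1, tau = 0.46, waves = w, seed = 1)
time_averaged_dc(traj)
```

## Inference

`bin_edge_fraction()` bins observed DC-ratios into 50-μm diameter bins and
counts edge (DC > 0.5), centre (DC < 0.2) and intermediate droplets; the
plotted edge fraction is `n(edge)/n(total)` with intermediates kept in the
denominator, because the published per-bin histograms colour all three
classes and derive the probability from the full bin. The alternative
`edge/(edge+center)` denominator is available behind a flag; with the
default generator the two differ negligibly because intermediates are rare.

`fit_edge_probability()` minimizes unweighted squared residuals of $p(D)$ at
the bin centres (a binomially weighted option exists), restarted from a
3×3 grid of initial values ($L \in \{2, 6, 12\}$ μm,
$\tau \in \{0.05, 0.5, 2\}$ s) under box bounds $L \in [0.5, 50]$,
$\tau \in [0.005, 50]$; the best converged start wins. $D_c$ is then
extracted from the fitted curve by the same bisection used everywhere
(tolerance $10^{-6}$ in probability, bracket 1–2000 μm, with a monotonicity
check before solving). Two numerical notes: the $(L, \tau)$ pair is only
weakly identified — a longer $L$ can trade against a slower $\tau$ — but
$D_c$ is stable; and evaluating the model at arithmetic bin centres while
diameters are log-uniform within bins biases fitted $D_c$ upward by about
2%, which is inherent to the binned procedure rather than to the optimizer.

The Kolmogorov–Smirnov comparison (`ks_compare()`) restricts both samples to
droplets of 50–150 μm diameter — around the control transition — and uses
asymptotic p-values, adequate at the ~10² sample sizes involved.

```{r fit}
obs <- generate_cohort(176, seed = 42)
fit <- fit_edge_probability(bin_edge_fraction(obs), w)
glance(fit)
```

## Image quantification

The imaging stage mirrors standard region-properties workflows: Otsu
binarization by default (a fixed threshold can be configured — the published
analysis states only "binarization"), connected-component labelling,
intensity-unweighted centroids in a 0-based pixel-centre convention, and
radii from the equal-area disk $R = \sqrt{A/\pi}$. The DC-ratio is the
centroid distance over the droplet radius.

Kymographs are sampled bilinearly along a fixed line through the droplet
and analysed in two stages: frame-to-frame spatial cross-correlation and
temporal autocorrelation anchor a global slope and period, then individual
wave events are detected just inside the boundary (the detection band adapts
to the slope so that fast ridges are not missed between frames) and each of
the first three ridges is tracked inward to fit its initial slope, covering
the first third of the transit before the terminal deceleration regime.
Velocity and period are reported as mean ± SD over those three events,
matching how the published values were averaged.

Filament morphometry binarizes a fluorescence-like image, keeps skinny
unbranched components (second-moment ellipse eccentricity > 0.9) of
reasonable size (area < 1300 px), thins each to a one-pixel skeleton
(Zhang–Suen) and reports length as skeleton pixel count × pixel size. The
pixel-count rule matches the stick-area convention of the original
measurement; it undercounts diagonal runs by up to $\sqrt{2}$, and blunt bar
ends erode by a pixel or two during thinning — the synthetic generator
therefore records its ground truth in the same pixel-count metric.
`top_fraction_mean()` implements the "top 5% average" summary
(mean of the `ceiling(0.05 n)` largest lengths).

## Synthetic data: what it emulates, and what it does not

`generate_cohort()` draws droplet diameters log-uniformly on 16–330 μm
(emulsification yields poly-disperse droplets spanning an order of
magnitude; no distribution is reported, and log-uniform spreads observations
across bins), cluster diameters proportional to droplet diameter
(slope 0.25–0.31 by condition, truncated Gaussian noise of 5% of $D$), and
the positioning state from a Bernoulli draw of $p(D)$. Edge-state DC-ratios
scatter around $1 - D_\mathrm{cluster}/D$ (cluster touching the boundary,
SD 0.05); centre-state DC-ratios are half-normal with scale 0.05. These
noise scales are explicit configuration, not claims about experimental
noise structure. Filament lengths are exponential with the rate chosen in
closed form so that the expected top-5% mean matches the configured target
(5.7 μm control, 3.2 μm gelsolin, 6.0 μm mDia2); only the top-5% statistic
is constrained by data, the family is a modelling choice.

Synthetic images (droplet frames, kymographs, filament fields) carry their
ground truth as attributes and in YAML sidecars next to the TIFFs. They
emulate geometry and sampling, not microscopy: no point-spread function, no
background gradients, no organelle texture, and strictly two-dimensional
scenes. Passing round-trip tests therefore demonstrates that the
quantification chain is unbiased on clean geometry at realistic sampling
(3-s frames, ~1 μm pixels), not that it is robust to every artefact of real
micrographs.

## Problem sizes and numerical choices

The test-suite and consistency checks use: $10^4$ Monte-Carlo trials per
percolation comparison (3-binomial-SE agreement across $N = 1\ldots10$,
$T/\tau \in \{1, 5, 20\}$); 50 cohort replicates of $n = 176$ droplets for
transition-diameter recovery; 200 seeds per diameter for the simulator's
edge fractions at $0.5\,D_c$ and $2\,D_c$, with 40-seed grids for the
parameter trends; and 1800-s trajectories at `dt = tau`. These sizes hold
every stochastic comparison to ~1% Monte-Carlo noise while keeping a full
run in tens of seconds on one core. Bisection tolerances are $10^{-6}$ in
probability; parameter agreement between `tau` and supplied rate constants
is enforced to a relative $10^{-9}$.

## Known limitations

* The wave is parameterized by its printed affine fits, not derived from
  active-gel theory; the maturation time of the first ring is absorbed into
  the period intercept, and the terminal deceleration of fronts near the
  cluster is not modelled.
* The simulator's event scheme is a reconstruction (choices documented
  above); outward transport speed is not experimentally constrained.
* Whether percolation restarts from partial occupancy after a wave passes
  is unknown; the process resets fully each period.
* Hydrodynamics, membrane deformation, droplet migration and
  oscillatory-cluster force balance are out of scope.
* Exact small-sample KS p-values are not implemented.
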