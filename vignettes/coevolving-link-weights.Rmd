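---
title: "Coevolution of strategies and link weights in the spatial prisoner's dilemma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coevolution of strategies and link weights in the spatial prisoner's dilemma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`coevoPD` simulates the weak prisoner's dilemma on an L x L square lattice
with periodic boundaries and Moore neighborhoods (eight neighbors per
site, N = L^2 players).  Each player is a cooperator (C) or defector (D).
The pairwise payoff to the focal player is

|        | vs C   | vs D |
|--------|--------|------|
| **C**  | R = 1  | S = 0 |
| **D**  | T = b  | P = 0 |

with temptation 1 < b < 2, so defection dominates in a well-mixed
population and b measures the strength of the dilemma.

Every undirected lattice link carries a symmetric weight w_xy, initially
1 and confined to the closed interval [1 - delta, 1 + delta] with
0 <= delta <= 1.  Weights express how much a relationship amplifies or
attenuates what is earned through it: the utility of player x is the
weighted payoff sum over its eight neighbors,

U_x = sum_{y in Omega_x} w_xy P_xy.

### The asynchronous elementary step

One elementary Monte Carlo event does, in order:

1. draw a focal player x uniformly at random;
2. compute x's eight pairwise payoffs P_xy and its utility U_x with the
   current weights;
3. adjust x's eight link weights: a link to a neighbor that paid x
   strictly more than x's mean pairwise payoff, mean(P_x.) over the eight
   games, is reinforced by +Delta; a link that paid strictly less is
   punished by -Delta; the result is clamped into [1 - delta, 1 + delta].
   An exact tie can occur only when all eight payoffs are equal (a
   strategy-uniform neighborhood); it discriminates nothing and leaves the
   link unchanged;
4. draw one neighbor y uniformly from the Moore neighborhood;
5. recompute U_x and compute U_y with the post-adjustment weights (the
   adjusted link is shared, so y feels it immediately);
6. if U_y > U_x, x adopts y's strategy with probability
   W = min(1, (U_y - U_x) / (D k_>)), where D = T - P = b is the maximal
   payoff difference and k_> = 8 the larger degree of the pair.  Ties and
   deficits keep the current strategy.

One Monte Carlo step (MCS) is N such events — focal players drawn with
replacement, so each player is selected once on average.  With Delta = 0
or delta = 0 every weight stays pinned at 1 and the dynamics reduce
exactly to the classical spatial prisoner's dilemma; the package asserts
this reduction by trace-identity against an independently coded classical
implementation under a shared RNG stream.

### Design choices where the rule left room

The reinforcement **reference level** is the mean of the eight raw
pairwise payoffs, not the per-link average of the weighted utility.  The
two readings differ sharply: a weighted reference is self-referential —
inside a cooperative domain it rises with the very weights it controls,
creating a feedback that pins each player's weighted utility near its
unweighted value and suppresses the cooperation-promoting heterogeneity
the weight dynamics are meant to create (in simulations it caps the
rescue at a mixed state and extinguishes cooperation at Delta/delta = 1).
The payoff-mean reference asks the natural question — *which partners pay
me above my average game?* — and produces the model's characteristic
phenomenology: a dominance plateau at intermediate amplitude, a middle
coexistence level at large amplitude, and dip-and-recovery at very small
amplitude.

**Ties** in the weight rule occur exactly when all eight payoffs are
equal, i.e. in strategy-uniform neighborhoods, where reward and
punishment are meaningless; the link is left unchanged.  Punishing ties
instead would make uniform cooperator domains erode their own bonds, and
rewarding them would inflate links that discriminate nothing; both
distort the interface competition that decides the outcome.

**Ties in imitation** (U_y = U_x) keep the current strategy: only a
strict utility advantage is imitated.

**Probability clipping**: weighted utilities reach 8 (1 + delta) b while
the traditional normalizer D k_> = 8 b is inherited from the unweighted
rule, so the raw ratio can exceed 1; it is clipped at 1.

**Update timing**: the utilities compared in step 6 use the
post-adjustment weights, following the strict order of the elementary
step (payoffs, then weights, then imitation).  Payoffs are recomputed
from scratch every event; nothing is accumulated across events.

**RNG contract**: every source of randomness draws from R's global
stream in the frozen order *focal uniform, neighbor uniform, adoption
uniform (drawn only when U_y > U_x)*.  The compiled kernel consumes the
same stream as the pure-R reference stepper, so single runs are
reproducible bit-for-bit from their seed, and the pure-R and compiled
paths are trace-identical.  Experiment drivers derive per-replicate
sub-seeds from one global seed by a fixed Lehmer step
(`split_seed()`), so adding replicates never perturbs existing ones.

**Floating point**: weights accumulate in double precision; the clamp
uses closed-interval comparisons with no epsilon.  Utility accumulation
order is fixed (neighbor-table order) so R and C++ agree bit-exactly.

## Parameters that matter

| symbol | meaning | default / typical |
|--------|---------|-------------------|
| b | temptation to defect, dilemma strength | 1.34 (time courses), swept in (1, 2) |
| delta | weight-bound half-width, in [0, 1] | 0.4 (0.8 for wide-amplitude sweeps) |
| Delta | per-event weight step, >= 0 | 0 - delta |
| Delta/delta | link-weight amplitude, the key control parameter | swept over [0, 1] |
| L | lattice side (N = L^2 players) | 100 full scale, 50 desk scale |
| total_mcs | Monte Carlo steps | 61000 full, 5000 desk |
| measure_window | trailing MCS averaged for the stationary level | 1000 full, 500 desk |
| replicates | independent realizations | 10 full, 3 desk |

`full_protocol()` returns the full-scale configuration; the package's
routine experiments and tests use `desk_protocol()` (50 x 50, 5000 MCS,
500-MCS window, 3 replicates).  The desk scale was chosen once as the
smallest protocol whose stationary regimes (extinction, dominance
plateau, middle level) are cleanly resolved; a finite-size spot check in
the test suite verifies that stationary levels at L = 50 and L = 100
agree within two standard errors.

## What the simulator shows

At the desk scale with b = 1.34, delta = 0.4 (all of this is recomputed
by the test suite and `scripts/acceptance.R`):

* **Traditional case** (Delta = 0): cooperation collapses to 0; scanning
  b shows cooperators die out near b ~ 1.24.
* **Intermediate amplitude** (Delta/delta ~ 0.2 - 0.6): cooperation
  climbs directly from the prepared half-and-half state to complete
  dominance, with no initial dip — the interface cooperators accumulate
  strong internal bonds faster than defectors can exploit them.
* **Large amplitude** (Delta/delta = 1): cooperation first expands, then
  settles at a middle coexistence level (~0.7 - 0.8): large steps also
  hand defectors strong exploitation links, fragmenting the cooperative
  clusters.
* **Very small amplitude** (Delta/delta ~ 0.005): the initial defector
  attack shrinks cooperation before slowly built heterogeneity lets it
  recover — the classical negative feedback reappears.

```{r}
library(coevoPD)

cfg <- desk_protocol(b = 1.34, delta = 0.4, Delta = 0.2,
                     init_mode = "half_plane", total_mcs = 3000,
                     measure_window = 500)
run <- run_simulation(cfg, seed = 1, snapshot_steps = c(0, 800, 1300, 3000))
run$stationary        # 1: complete dominance
min(run$trajectory$rho_c)  # 0.5: no initial dip

sw <- sweep_amplitude(1.34, 0.4, seq(0, 1, by = 0.1),
                      config = desk_protocol(), seed = 1)
aggregate_sweep(sw, by = "ratio")  # peak at ratio ~ 0.2-0.5
```

## The weight distribution and its variance

`weight_summary()` histograms the 4 L^2 edge weights (default binning is
aligned to the attainable lattice {1 + k Delta} clamped to the bounds, so
every attainable value maps to exactly one bin) and reports the
population mean and variance.  A hard bound follows from the clamp: a
variable confined to an interval of half-width delta has variance at most
delta^2 (attained by the two-point distribution at the bounds); the
summary asserts it.

Note one structural consequence of the tie rule: once the population
absorbs into full cooperation, every payoff equals the mean payoff, and
the weight field freezes at whatever mosaic the transient left behind.
The weight distribution keeps evolving only while strategies coexist, so
amplitudes that preserve coexistence (large Delta/delta) retain more
weight heterogeneity in the stationary state than amplitudes that drive
cooperation to fixation.

## What the generator emulates — and what it does not

There is no external data: the simulator itself generates every state the
package analyses, under the study conditions fixed in the protocols
above.  The model is a stylized abstraction — a regular lattice with
constant degree 8, one payoff matrix for all pairs, weights bounded in a
fixed symmetric interval, and no noise in the imitation rule beyond its
probabilistic acceptance.  Passing tests therefore demonstrate properties
of this model class, not of any empirical social network: real
interaction networks have heterogeneous degree, directed and asymmetric
dependencies, and nonstationary membership, all outside scope here.

## Numerical and degenerate cases

* `delta = 0` with `Delta > 0`: the clamp collapses to [1, 1]; dynamics
  are classical.  The amplitude Delta/delta is undefined and requesting
  it (`weight_ratio()`, ratio-parameterized sweeps) is an error.
* `half_plane` initial states require even L so the initial cooperation
  fraction is exactly 0.5; odd L is rejected.
* All-C and all-D strategy fields are absorbing (imitation can only copy
  the same strategy); runs may optionally stop early on fixation
  (`stop_when_uniform`), extending the trajectory as a constant.  This
  freezes the weight field too, so it is off by default and off whenever
  the weight distribution is the observable.
* Extinction thresholds are extracted from a b-scan as the largest grid b
  with mean stationary rho_C above a tolerance (default 1/N^2), linearly
  interpolated towards the first grid point at or below it; an
  unbracketed transition is reported as out-of-range (`NA` with a status
  attribute), never as a number.  Raising the tolerance can only lower
  the threshold.

## Known limitations

* The dominance plateau makes the argmax of the amplitude sweep sit at
  the plateau's left edge on the default grid; finer grids resolve the
  plateau, not a sharper peak.
* Near the extinction boundary, single runs fixate stochastically;
  threshold estimates use replicate means and grid interpolation, and are
  only as fine as the b grid (0.02 by default).
* The trailing-window stationary average can slightly undershoot 1 when
  absorption into full cooperation happens inside the window.
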