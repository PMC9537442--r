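---
title: "Evaluating landscape connectivity models against simulated movement"
author: "connscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating landscape connectivity models against simulated movement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(connscape)
```

## The problem

Resistance-based connectivity models — factorial least-cost paths (FLCP),
resistant kernels (RK) and circuit-theory current density (CS) — are the
workhorses of connectivity mapping in conservation science, yet they rest
on very different assumptions about how organisms move. `connscape`
evaluates them against a *known truth*: a density-of-movement surface
aggregated from many stochastic, individual-based walks whose behavioural
rules (energy limitation, attraction to low resistance, mortality risk,
directional persistence, destination bias, multi-scale perception) are
fully controlled. Because the generating process is known, differences
between a model's prediction and the simulated density measure genuine
model error rather than unexplained ecology.

## The movement model

A walk starts at a source pixel on a resistance surface $r$ (values in
$[1, 100]$, cost per unit distance) and at each step draws one of its
admissible Moore neighbours from the mixture

$$P = (1 - C' - D)\,P_\mathrm{mech} + C'\,P_\mathrm{persist} +
D\,P_\mathrm{dest}, \qquad C' = C\,(1 - D),$$

where $P_\mathrm{mech} \propto 1/r_j$ when the attraction mechanism is
active (uniform otherwise), $P_\mathrm{persist}$ is a point mass on the
neighbour continuing the previous direction, and $P_\mathrm{dest}$ is a
point mass on the admissible neighbour closest to the destination. When
no admissible continuation exists, the persistence mass folds back into
the mechanism term, so the distribution always sums to one. The
reweighting $C' = C(1-D)$ keeps the mixture convex for any
$C, D \in [0,1]$.

Moving from pixel $i$ to $j$ costs
$\mathrm{len}(i,j)\,(r_i + r_j)/2$ with $\mathrm{len} = \sqrt 2$ on
diagonals — the standard cost-distance convention, used identically by
the walker and by all three predictors so that energy budgets, dispersal
thresholds and cost distances are commensurable. A walk ends at the
first of: the step cap (500 by default); energy exhaustion (the walk
stops *before* a move whose cost would reach the budget $E$, so the
realised cost never exceeds $E$); a per-step mortality event on arrival
at pixel $j$, with hazard $1 - \exp(-\beta\,\mathrm{risk}_j /
\max(\mathrm{risk}))$; or arrival at the destination when $D > 0$.

Two defaults require justification because the published experiment does
not state them. The energy budget defaults to $E = 250 \times$ the
median (focal-scaled) resistance — the cost of roughly half the step cap
on typical terrain, so energy termination bites without dominating. The
hazard scale $\beta$ defaults to $\log 2 / (250\,m)$ with $m$ the
median relative risk, so a 250-step walk on median terrain survives with
probability one half.

## The three predictors

All three operate on the 8-connected pixel cost graph:

* **`factorialLCP()`** extracts one minimum-cost path per unordered
  source pair (deterministic tie-breaking in a fixed neighbour order)
  and counts paths per pixel.
* **`resistantKernels()`** sums per-source kernels
  $K_s(p) = \max(0,\, 1 - \mathrm{cd}_s(p)/T)$, where $\mathrm{cd}_s$ is
  the cost distance from source $s$ alone and $T$ a dispersal threshold.
* **`circuitCurrent()`** treats edge conductances $1/w(i,j)$ as a
  resistor network; for every source pair a unit current is injected and
  withdrawn, node potentials solve the graph Laplacian system (sparse
  Cholesky, residual checked against `tol`), and a pixel's current is
  half the sum of absolute incident edge currents (the full injected
  current at the two terminals), summed over pairs.

### The kernel dispersal threshold

The natural impulse is to set $T$ equal to the walker's energy budget
$E$. That is dimensionally consistent but wrong in substance: a random
walk's *accumulated cost* grows linearly in its number of steps $S$,
while its *net displacement* — the quantity a dispersal threshold
describes — grows only as $\sqrt S$. With $T = E$ the kernels reach an
order of magnitude past any simulated disperser and degenerate towards a
constant surface. `kernelThreshold()` therefore sets
$T$ to the 0.3 quantile of the minimum cost-distance surface (the
kernels jointly reach the nearest 30 % of the landscape — comfortably
resolving the top-decile overlap statistic), capped at the
displacement-equivalent cost radius $\sqrt{1.5\,S}\,\tilde r$ (mean
squared move length 1.5 on the Moore grid; $\tilde r$ the median
resistance; $S$ the expected step count from `expectedPathSteps()`,
which accounts for the step cap, the energy budget and the mortality
hazard). The cap keeps $T$ responsive to scenarios with severely limited
dispersal, while the coverage term sets the scale on ordinary ones.

## Accuracy statistics

`compareSurfaces()` min-max normalises both surfaces and reports the
per-pixel RMSE (bounded in $[0,1]$), the Pearson correlation over all
pixels, and the overlap of the top-$q$ (default 10 %) highest-valued
pixel sets, $|A \cap B|/K$ with $K = \lfloor qN \rfloor$ and ties broken
by pixel index. Min-max normalisation makes the statistics invariant to
each model's arbitrary output scale (path counts, kernel sums, amperes);
the alternative reading of a "total error divided by the number of
pixels" is not bounded the same way and is deliberately not used. Note
that at modest replication the density surface holds small integer
counts with large tie blocks at the top-$K$ boundary, which deflates
overlap for *all* models; the index tie-break keeps it deterministic.

## The factorial experiment

`experimentConfig("first")` crosses 7 resistance surfaces with 7
movement-mechanism combinations, spatial scales $\{1,3,5,7\}$, scaling
functions $\{\mathrm{mean},\mathrm{max},\mathrm{min}\}$ and
autocorrelation $C \in \{0, 0.35, 0.75\}$ (no destination bias): 1764
scenarios. `experimentConfig("second")` fixes scale 1, focal mean and
$C = 0.2$ and crosses the surfaces and mechanisms with
$D \in \{0.1, 0.3, 0.6\}$: 147 scenarios, 1911 in total. At full scale
each scenario aggregates 100 paths from each of 100 sources (10,000
paths). Destinations in the second analysis are unstated in the original
design; here each path is assigned a uniformly drawn *other* source
point under its own sub-seed, keeping destinations heterogeneous and
inside the experiment.

Seeding is hierarchical and content-addressed: the master seed plus a
hash of the scenario identifier gives the scenario seed, and each
(source, replicate) pair derives its own sub-seed, so any single path is
reproducible in isolation and resumed or subset runs yield bit-identical
tables.

### Synthetic surfaces

The complexity ladder is generated rather than estimated
(`generateSurfaceSuite()`): surface 1 is a uniform background with three
high-resistance barriers, each pierced by a 3-pixel gap (exactly two
resistance values; every pixel reachable at finite cost); surfaces 2–7
are Gaussian random fields sharing one white-noise realisation, filtered
at spectral exponents falling from 2.2 to 1.0 and rank-quantised to 6,
12, 24, 48, 96 and finally a continuous spread of resistance levels in
$[1, 100]$. Sharing the noise realisation makes the roughness ladder
deterministic in the exponent, and rank-based quantisation fixes the
histogram exactly, so both complexity measures (32-bin entropy, mean
absolute neighbour difference) are non-decreasing along the suite for
every seed — an invariant the test suite asserts. What these surfaces do
*not* emulate: anisotropy, land-cover class structure, or any empirical
resistance estimation; conclusions about those features are outside what
passing tests can show.

```{r surfaces, eval = FALSE}
suite <- generateSurfaceSuite(64, 64, 7, seed = 1)
op <- par(mfrow = c(1, 3), mar = c(1, 1, 2, 1))
image(suite[[1]]); image(suite[[4]]); image(suite[[7]])
par(op)
```

## A worked desk-scale example

The desk profile (`deskProfile()`) runs the same factor grids on 64×64
surfaces with 25 sources and 10 paths per source — sized so the full
1764-scenario first analysis completes in about two minutes on one CPU
(the problem sizes quoted throughout this vignette are this profile).

```{r experiment, eval = FALSE}
tab <- runExperiment(deskProfile("first", surfaceSeed = 1, masterSeed = 1))
summarizeByModel(tab)
#>     model      rmse   pearson   overlap
#> 2    flcp 0.2565160 0.1146373 0.2077519
#> 3 kernels 0.2398183 0.4145987 0.3504912
#> 1 circuit 0.1814387 0.3530122 0.2953113
```

The orderings mirror the published full-scale findings: circuit current
attains the lowest error, resistant kernels the highest correlation and
overlap, and factorial least-cost paths trail on every statistic. The
absolute correlations and overlaps sit well below the published
full-scale values — expected, because at 64×64 a 500-step walk spans a
third of the grid (an eighth at 256×256), sources are relatively closer,
and 250 paths per scenario leave far more counting noise than 10,000.

```{r synthesis, eval = FALSE}
Y <- as.matrix(tab[, c("rmse", "pearson", "overlap")])
X <- data.frame(mechanism = factor(tab$mechanism),
                surface = factor(tab$surface_id),
                scale_n = factor(tab$scale_n),
                scale_fn = factor(tab$scale_fn),
                C = factor(tab$C), model = factor(tab$model))
variancePartition(Y, X, list(X1 = "mechanism", X2 = "surface",
                             X3 = c("scale_n", "scale_fn", "C"),
                             X4 = "model"))
#> Variance partitioning (adjusted R2 components):
#>   unique:X4                  0.3441
#>   unique:X3                  0.1775
#>   unique:X1                  0.1189
#>   unique:X2                  0.0226
#>   ...
#>   residual                   0.3391
```

Model choice (X4) is the dominant factor, ahead of the movement
parameters (X3), the mechanism (X1) and the surface (X2) — the same
qualitative pattern as the published partition, though the surface
effect is weaker at desk scale.

## Multivariate synthesis: implementation notes

`rdaConstrained()` and `ccaConstrained()` are implemented directly (QR
projection of the response onto the dummy-coded design, SVD of the
fitted values; CCA applies the chi-square standardisation with row-mass
weights first) and are verified in the test suite against dense
brute-force oracles and against vegan to $10^{-8}$. Responses are
standardised to unit variance before RDA because the three statistics
have unlike scales; for CCA, which requires non-negative input, each
response column is min-shifted to zero (`minShift()`) — this preserves
within-column ordering but does change chi-square row profiles, a known
divergence risk of feeding signed statistics to a correspondence
method. Adjusted $R^2$ uses Ezekiel's correction; shared
variance-partition components follow by Möbius inclusion–exclusion over
group subsets and may be negative, as usual for adjusted partitions.
Factors with few sampled levels (scale, $C$, $D$) are coded categorical
throughout. `anovaFactorial()` fits main effects and two-way
interactions via `aov()`; saturated higher-order models are not
estimable at one replicate per cell.

## Numerical choices and degenerate inputs

* Dijkstra shortest paths (compiled) use a fixed neighbour order and
  strict-improvement predecessor updates, making least-cost paths
  deterministic under cost ties.
* The circuit solve pins one non-source reference node, factorises the
  reduced Laplacian once per surface and reuses it across all source
  injections; the relative residual is checked against `tol` (default
  $10^{-8}$) and a warning is raised if exceeded. Grids with strictly
  positive finite resistance are always connected, so component
  handling never arises in practice.
* Constant grids normalise to all zeros and yield an undefined (NA)
  Pearson correlation rather than an arbitrary value.
* Eigenvalues below $10^{-12}$ of the leading one are truncated to keep
  ordination ranks stable.

## Known limitations

* The simulated truth deliberately terminates a walk on arrival at its
  destination. Under strong destination bias this makes paths short and
  the density surface sparse, and after min-max normalisation the RMSE
  *falls* as $D$ rises, whereas the published trend (with an
  unpublished walker whose termination rule is unknown) has error
  rising with $D$; the top-decile overlap falls with $D$ in both.
* Desk-scale results reproduce orderings, not magnitudes; quantitative
  agreement with full-scale pooled statistics requires the full
  256×256 / 10,000-path profile, which takes hours on one CPU.
* The walker's functional forms (mixture weights, hazard, energy
  accounting) are explicit re-specifications of behaviours the original
  simulation tool documents only informally; they are not claims about
  that tool's internals.
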