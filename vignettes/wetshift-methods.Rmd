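---
title: "Methods: change accounting and SSA-tuned wetland driver attribution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: change accounting and SSA-tuned wetland driver attribution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wetshift)
```

`wetshift` answers two questions about a multi-epoch categorical land-cover
series: *how* did natural wetland (NAW) shift among the eight land classes,
and *which drivers explain the shift*. This vignette records the models, the
parameter choices, and the design decisions taken where the methodology left
room.

## Change accounting

**Dynamic index.** For a class with areas $U_a$ (period start) and $U_b$
(period end) over $T$ years,
$$K = \frac{U_a - U_b}{U_a}\cdot\frac{1}{T}\cdot 100\%.$$
As written, $K < 0$ for an area *increase*, while dynamic degrees are
conventionally reported as positive rates of change. `dynamic_index()`
therefore returns both the formula-literal `K_signed` and the magnitude
`K_abs`; reported values and the packaged reference checks compare on
`K_abs`. $U_a = 0$ raises an error rather than returning an infinity.

**Transfer matrix.** $S_{ij}$ is the area occupied by class $i$ at the start
and $j$ at the end, obtained by cross-tabulating co-registered rasters over
the shared valid mask and scaling by the cell area. Conservation is exact by
construction: the grand total equals the masked area and the margins equal
the per-epoch area tables. A cell valid in only one epoch is counted in
neither margin and triggers a warning — a policy choice; dropping or
single-counting such cells would silently break conservation.

**Transformation intensity.** On a square analysis grid (default block side
10 000 m),
$$R = \frac{\Delta S}{S_{grid}\cdot T}\cdot 100\%,$$
where $\Delta S$ is defined here as the area of cells whose class label
changed between the epochs, optionally restricted to transitions touching a
focus class set (the wetland-focused variant drives the sampling weights).
Edge blocks that do not tile evenly use their actual covered area as
$S_{grid}$ and are flagged, rather than being dropped; dropping them would
bias statistics along the study-area boundary. The intensity grid is
exported as CSV (plus an in-memory matrix via `intensity_matrix()`); no
smoothing or interpolation is applied — interpolated display maps are a
cartographic concern outside this package's scope.

## The synthetic landscape generator

No public input reproduces the proprietary multi-source rasters this kind of
analysis is run on, so validation uses a generative stand-in with known
ground truth: an annual Markov process on the 8 classes in which the
transition probability of cell $c$ from class $i$ to $j$ is the configured
baseline rate, shifted on the log-odds scale for wetland-gain
($j = \mathrm{NAW}$) and wetland-loss ($i = \mathrm{NAW}$) transitions:
$$\mathrm{logit}\,p_{ij}(c) = \mathrm{logit}\,p^0_{ij} +
\sum_d \beta_d\, z_d(c) + \varepsilon_c,\qquad
\varepsilon_c \sim N(0, \sigma^2).$$
The logistic link keeps probabilities valid without clipping; if a cell's
off-diagonal probabilities exceed 1 in total they are renormalized and the
remainder is the stay probability, so class areas are conserved exactly at
every step. Multi-year epochs are compounded from annual substeps, matching
the 5-year spacing of the monitoring datasets this emulates.

Driver surfaces are Gaussian random fields (white noise circularly convolved
with a Gaussian kernel), standardized to zero mean and unit variance; the
topographic drivers (ELE, SLO) are flagged static. The default study
conditions are a 200 × 200 cell landscape at 1 km² per cell — so the 10 km
analysis grid yields 20 × 20 blocks — seven epochs 1990–2020, correlation
length 25 cells, baseline wetland gain 0.8%/yr from GRL/DRA/UNL and loss
1.5%/yr to DRA/PAF, with gain driven by precipitation (strong) and
temperature (weak) and loss suppressed by road distance
(`default_transition_spec()`).

What the simulator does *not* emulate: classification error, spatially
correlated class patches in the initial map (cells are drawn independently),
temporally varying drivers, and policy-driven regime switches between the
degradation and restoration phases. Passing tests therefore demonstrate that
the chain recovers a known signal under clean conditions, not that it is
robust to interpretation error in real imagery.

## Sampling design

The "spatial balance" idea — weight training cells by wetland change while
limiting spatial clustering — is implemented as: weights proportional to the
per-block wetland-change density, a threshold $\tau$ at the 5th percentile
of the nonzero densities (type-1 quantile, so at most 5% of active blocks are
excluded), weighted sampling *without replacement*, and greedy rejection of
candidates closer than `min_separation` (default 1 block) to an accepted
block. All knobs are exposed. Two ambiguities were resolved as follows and
are configurable rather than asserted: the sampled unit is the analysis
block (not a sub-block point), and weights use wetland *change* density
(not wetland presence).

The response is $y = 100\,(A^{NAW}_{end} - A^{NAW}_{start})/A_{block}$,
the percentage of block area by which wetland changed, which keeps $y$
bounded in $[-100, 100]$; normalizing by the start wetland area instead
would be unbounded on blocks that gain wetland from near zero. The split is
seeded, `ceiling(0.8 n)` training rows against the remainder (500 → 400/100).

## The sparrow search algorithm

SSA is a population metaheuristic with three roles per iteration over a
$P$-sparrow swarm (defaults $G_{max} = 80$, $P = 50$, producer fraction 20%,
$SD = 5$ scouts, warning threshold $ST = 0.8$):

- **Producers** (best-ranked fraction): with per-iteration alarm
  $R_2 \sim U(0,1)$ below $ST$, rank-$i$ contracts multiplicatively,
  $X \leftarrow X\exp(-i/(\alpha G_{max}))$, $\alpha \sim U(0,1)$;
  otherwise $X \leftarrow X + Q$ with a single $Q \sim N(0,1)$ broadcast
  over dimensions.
- **Followers** (the rest, in rank order $i$): the worse half jump near the
  current worst, $X \leftarrow Q\exp((X_w - X)/i^2)$; the better half move
  beside the best producer, $X \leftarrow X_b + (|X - X_b|\cdot A^+)L$ with
  $A$ a random $\pm 1$ row vector and $A^+ = A^T/d$ its Moore–Penrose
  pseudo-inverse — i.e. the same signed average deviation added to every
  coordinate.
- **Scouts** ($SD$ random sparrows): if worse than the global best, relocate
  around it, $X \leftarrow X_b + \beta|X - X_b|$, $\beta \sim N(0,1)$;
  a scout at the global best moves relative to the worst with the
  $\varepsilon = 10^{-50}$ guard against division by zero when best and
  worst fitness coincide.

Interpretation decisions (the published formulations leave these open):
$X_b$ in the follower update is the rank-1 sparrow's position *after* the
producer phase, without a mid-iteration re-evaluation; scouts compare
against the global best/worst; out-of-box positions are clamped to the
bounds (the simplest scheme preserving the update semantics); the alarm
value is drawn $U(0,1)$ each iteration and compared against $ST$, whose
default 0.8 follows the stated initialization. A published "alarm value
$R_2 = 0.8$" conflates the random draw with the threshold; treating 0.8 as
the threshold default and drawing $R_2$ randomly preserves both roles.

Integer hyperparameters use continuous relaxation with rounding at each
fitness evaluation, and the tuner caches fitness on the rounded pair so the
swarm never refits an already-scored configuration. The best-ever evaluated
point is tracked greedily, making the reported history monotone — verified
on every run in the test suite, alongside a bit-for-bit equivalence check
against an independent straight-line transcription of the update equations
under shared seeds.

## Boosted attribution

The regression engine is XGBoost with squared-error loss — the regularized
objective $\sum_i l(y_i, \hat y_i) + \gamma N + \tfrac{\lambda}{2}\sum_j
w_j^2$ optimized by second-order approximation — run single-threaded with a
fixed engine seed for exact reproducibility. Engine defaults $\gamma = 0$,
$\lambda = 1$ are kept (no values are published) and exposed in
`boost_config()`. The tuner searches depth $H \in [2, 15]$ and tree count
$M \in [10, 300]$ by default with validation RMSE as fitness, mirroring the
published protocol (learning rate fixed at 0.3).

Contributions are normalized feature importances summing to 100. The default
notion is **gain** (total objective improvement from a feature's splits);
split-frequency (`weight`, the count-based definition) and `cover` are
selectable, and every report records which was used. Gain is the standard
contribution notion; frequency over-credits shallow, often-split features.
Note that *literally duplicated* feature columns defeat any importance-based
symmetry expectation: the engine's deterministic tie-breaking routes all
gain to one copy. The symmetry test therefore uses two symmetric-role
features rather than duplicates.

$R^2$ is $1 - SS_{res}/SS_{tot}$ on the evaluation set (NA for a constant
response). Cross-validation uses seeded folds whose sizes differ by at most
one; $k = n$ gives leave-one-out, where per-fold $R^2$ is undefined (size-1
folds) and reported as NA.

## Problem sizes and numerical choices

The validation suite runs at desk scale, chosen once: 200 × 200 landscapes
for conservation checks (20 replicates), 100 × 100 landscapes over 1990–2005
for importance recovery (20 replicates per scenario; dominant driver
`PRE = 2.0`, and a 2:1 scenario `PRE = 1.6, TEM = 0.8`, log-odds noise 0.3),
tabular samples of $n = 500$ at true $R^2 = 0.8$ for the CV benchmark, and a
300-row fixed sample against an exhaustive 6 × 6 grid for the tuning oracle.
The demonstration configuration (`default_run_config()`) reduces the SSA
budget to $G = 10$, $P = 12$ and samples 250 of the 400 blocks; the
full-size defaults remain available through `ssa_config()`.

Numerical details worth knowing: areas from rasters are in km² (the packaged
reference series is in 10³ km² as printed; the dynamic index is scale-free);
TIFF round-trips are exact for 8-bit class codes; the random-field FFT
convolution wraps at the edges; and all stochastic entry points take a
`seed` and restore the caller's RNG state.

## Known limitations

- Raster exchange is baseline TIFF plus a plain-text sidecar; reprojection,
  heterogeneous grids and on-the-fly resampling are out of scope
  (co-registration is a precondition, checked, not repaired).
- Contributions are importance shares, not causal effects; correlated
  drivers share credit in ways importance normalization cannot disentangle.
- The simulator's stationary transition process cannot reproduce
  regime-switching histories (decline then recovery) within one spec;
  analysis periods are windows over one stationary process.
- Published per-driver percentages from the real proprietary rasters are not
  recomputable here; the package instead validates the *properties* those
  tables must satisfy and the chain's ability to recover known synthetic
  ground truth.
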