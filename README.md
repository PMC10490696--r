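# wetshift

Quantifying how natural wetlands shift within a changing landscape — and why.

`wetshift` implements a complete analysis chain for multi-epoch categorical
land-cover data on the eight-class scheme commonly used for the plains of
Northeast China (dryland DRA, paddy field PAF, woodland WOL, grassland GRL,
unused land UNL, construction land COL, natural wetland NAW, reservoirs and
ponds REP):

1. **Change accounting.** The single land-use dynamic index of a class over a
   period,

   `K = (Ua − Ub) / Ua × 1/T × 100%`  (percent per year),

   the class-to-class **area transfer matrix** `S[i, j]` (area occupied by
   class *i* at the start epoch and class *j* at the end), and the gridded
   **transformation intensity**

   `R = ΔS / (S_grid × T) × 100%`

   computed per 10 km × 10 km analysis block, where `ΔS` is the changed area
   inside the block and `S_grid` the block's covered area.

2. **Spatially balanced sampling.** Eleven drivers (elevation ELE, slope SLO,
   temperature TEM, precipitation PRE, distance to roads DRN, population
   density PDD, GDP, and the DRA/PAF/WOL/GRL area fractions) and the
   wetland-change response are aggregated onto the analysis grid; training
   blocks are drawn with weights proportional to wetland-change density,
   thresholded and separation-constrained, then split 8:2.

3. **SSA-tuned boosted attribution.** A gradient-boosted regression
   (squared-error loss with `γ`/`λ` regularization, learning rate 0.3) maps
   drivers to wetland change; its depth `H` and tree count `M` are tuned by a
   **sparrow search algorithm** (producers/followers/scouts, validation RMSE
   as fitness, defaults G = 80, P = 50, PD = 20%, SD = 5), validated by
   k-fold CV, and feature importances are normalized into per-driver
   **percentage contributions summing to 100** per analysis period
   (degradation, restoration, complete cycle).

Because real multi-source rasters of this kind are proprietary, the package
ships a driver-modulated Markov **landscape simulator**: per-cell transitions
into/out of the wetland class are shifted on the log-odds scale by
configurable driver effects, so the attribution chain can be validated
against a known ground truth.

## Worked example

The packaged reference area series (Northeast China Plain, 1990–2020,
10³ km²) reproduces the published wetland dynamics:

```r
library(wetshift)
dynamic_index(67.03, 98.78, 5)   # NAW 2005 -> 2010
#>      Ua    Ub T K_signed   K_abs
#> 1 67.03 98.78 5 -9.47337 9.47337
validate_reference_areas()
#>                                     check computed expected pass
#> 1  dynamic index |K| NAW 2005-2010 (%/yr)     9.47     9.47 TRUE
#> 2  dynamic index |K| UNL 2005-2010 (%/yr)    10.37    10.37 TRUE
#> 3     relative NAW increase 1990-2020 (%)    32.00    32.00 TRUE
#> 4        NAW share of total area 2020 (%)     8.00     8.00 TRUE
#> 5 NAW area increase 2005-2020 (10^3 km^2)    37.76    37.76 TRUE
```

The magnitude `|K|` is reported because the printed formula is negative for
an area increase. End-to-end on a synthetic landscape whose ground truth is
wetland gain driven by precipitation (strong) and temperature (weak), and
wetland loss suppressed far from roads:

```r
drivers <- make_driver_fields(c(200, 200), corr_len = 25, seed = 1)
init    <- make_initial_landscape(c(200, 200), seed = 2)
series  <- simulate_lucc_series(init, drivers, default_transition_spec(),
                                seq(1990, 2020, 5), seed = 3)
fit <- wetland_attribution(series, drivers, c(1990, 2020), "COM", n = 250,
                           ssa = ssa_config(rbind(depth = c(2, 8), trees = c(10, 120)),
                                            Gmax = 10, P = 12, SD = 2,
                                            integer_dims = 1:2, seed = 4),
                           cv_k = 5, seed = 5)
fit
#> Wetland driving-force attribution - period COM (1990-2020)
#>   samples: 250 blocks | tuned depth 2, trees 25 | validation RMSE 3.735
#>   validation R2 0.839 | 5-fold CV mean R2 0.851
#> <contribution_report> COM; importance = gain (percent, sums to 100.00)
#>  driver contribution
#>     DRN        47.19
#>     PRE        44.35
#>     TEM         2.34
#>     DRA         1.19
#>     ...
```

The two true drivers (DRN, PRE) absorb over 90% of the contribution, the
weak third (TEM) ranks next, and the nine uninformative drivers share the
remainder — the recovery the simulator is designed to make checkable.
`run_all(default_run_config())` executes the whole workflow (simulation,
change metrics, sampling, tuning, CV, contribution tables) for all three
periods from one configuration and writes every artifact as CSV/TIFF with a
run manifest. A thin command-line wrapper lives at `inst/cli/wetshift`.

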