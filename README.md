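# cbhkin — single-molecule kinetics of processive cellobiohydrolases

`cbhkin` analyses single-molecule fluorescence imaging experiments on
cellobiohydrolases (CBHs) degrading crystalline cellulose microfibrils, and
integrates the results into a kinetic summary of the elementary reaction
steps: binding, dissociation, processive movement, and bulk turnover.  It is
written for single-molecule enzymologists who have localized binding events
and tracks (CSV tables) and want the full chain from raw event lists to
component-resolved kinetic constants — and for method developers, who get a
synthetic-experiment simulator with known ground truth to validate every
stage by parameter recovery.

## The quantities at the core

For an enzyme at concentration $C$ observed for time $T$ on a fibril of
length $L$:

* binding rate constant $k_{on} = N/(C\,L\,T\,r)$ per fibril ($N$ bound
  molecules, $r$ the dye labeling ratio), units
  $\mathrm{M^{-1}\,\mu m^{-1}\,s^{-1}}$; its distribution over fibrils is
  decomposed into Gaussian peaks (bundle multiplicity), the lowest peak
  being the single-bundle $k_{on}$;
* dwell-time histograms fitted with
  $y(t) = A_f e^{-k_{off}^{fast} t} + A_s e^{-k_{off}^{slow} t}$, mode
  fractions from the decay areas $f_i \propto A_i/k_i$, optional
  photobleaching correction $k_{off} = k_{obs} - k_{bleach}$;
* translational rate $k_{tr}$ = first-to-last displacement / moving time;
  processivity $= v_{slow}\,\tau/\ell$ with $\ell = 1.0$ nm (cellobiose);
* per-mode constants $k_{on,i} = f_i\,k_{on}$ and
  $K_{d,i} = k_{off,i}/k_{on,i}$ (units M um); Michaelis–Menten fits
  $v = k_{cat}S/(K_m+S)$ of bulk assays; productive fraction
  $= k_{cat}/k_{single}$.

## Worked example

Feed the published per-construct constants (total `kon`, fast/slow `koff`,
mode fractions) through the table builder:

```r
library(cbhkin)
tab <- build_kinetic_table(cfcel6b_reference())
tab
#> Kinetic summary table (rendered at 2 significant figures)
#>  construct component kon_total  koff fraction kon_component      Kd fraction_pct
#>     Intact      fast   4.3e+08 0.850     0.33       1.4e+08 6.0e-09           33
#>     Intact      slow   4.3e+08 0.086     0.67       2.9e+08 3.0e-10           67
#>         CD      fast   1.7e+07 1.700     0.81       1.4e+07 1.2e-07           81
#>         CD      slow   1.7e+07 0.130     0.19       3.2e+06 4.0e-08           19
#>   FN3s-CBD      fast   2.0e+08 2.700     0.26       5.2e+07 5.2e-08           26
#>   FN3s-CBD      slow   2.0e+08 0.290     0.74       1.5e+08 2.0e-09           74
#>        CBD      fast   1.5e+08 3.100     0.30       4.5e+07 6.9e-08           30
#>        CBD      slow   1.5e+08 0.470     0.70       1.1e+08 4.5e-09           70
```

Each row is one construct x kinetic mode: `kon_component` is the share of
the binding rate constant attributable to that mode, and `Kd` its
dissociation constant.  The slow (hydrophobic-face, hydrolysis-relevant)
mode of the full-length enzyme has the highest affinity
(`Kd` $= 3.0\times10^{-10}$ M um); the isolated catalytic domain loses it:

```r
kd_fold_ratio(tab, "CD", "slow", "Intact", "slow")$reported
#> [1] 133
processivity(11.6, 4.6)$reported   # slow k_tr peak x moving-time constant / 1 nm
#> [1] 53
productive_fraction(2.4, 11.6)$fraction   # bulk kcat / single-molecule rate
#> [1] 0.2068966
```

Simulation-based recovery works the same way from the other end — generate
a synthetic movie, then estimate:

```r
truth  <- cfcel6b_truth("Intact")
cond   <- imaging_conditions(enzyme_conc = 50e-12, bleach_rate = 0)
field  <- make_fibril_field(200, 5, 1, c("1" = 1), seed = 1)
events <- simulate_binding(truth, field, cond, seed = 2)
fit    <- fit_exponential(collect_dwells(events, cond), 2)
fit
#> Exponential decay fit (2 component(s)), R^2 = 0.991
#>   fast: k = 0.9032 s^-1, fraction = 34.3%
#>   slow: k = 0.09049 s^-1, fraction = 65.7%
```

(true values: 0.85 and 0.086 s$^{-1}$ at 33% / 67%).

A YAML/JSON-driven `run_pipeline()` executes simulate → kon → koff → motion
→ table in one call and writes `report.json` + `kinetic_table.csv`; a thin
command-line front end with `simulate` / `kon` / `koff` / `motion` / `mm` /
`run` subcommands lives at `inst/scripts/cbhkin`.  The methods vignette
(`vignettes/single-molecule-cbh-kinetics.Rmd`) documents the models,
defaults and numerical choices.

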