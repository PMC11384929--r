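# bmpkin

Kinetics and dose-response analysis for biochemical methane potential (BMP)
assays.

BMP assays quantify the methane yield of a substrate under anaerobic
digestion, as cumulative CH4 volume per gram of volatile solids (VS) added,
logged by an automatic test system on a fixed sampling grid. `bmpkin` is for
experiments that probe how an additive — typically biochar, dosed in g per
litre of reactor volume — changes those kinetics, where two things must be
handled before any curve is interpretable: the inoculum's own residual
carbon has to be digested out (otherwise it confounds the substrate signal),
and replicate reactors at several doses have to be compared with a
scale-free statistic.

The package implements the full chain:

* **Stoichiometric ceilings** — the Buswell–Mueller balance converts a CHONS
  elemental analysis into theoretical ultimate methane (uBMP) and biogas
  potentials per g VS:
  `(c/2 + h/8 − o/4 − 3n/8 − s/4) CH4 + (c/2 − h/8 + o/4 + 3n/8 + s/4) CO2 + n NH3 + s H2S`,
  scaled to volumes at a configurable molar volume (default 22,400 mL/mol).
* **Depletion scheduling** — a first-order model
  `BMY(t) = uBMY (1 − e^(−kt))` of residual inoculum carbon decides, to the
  whole day, when a multi-feed assay reaches its *isolated-substrate phase*.
* **Phase processing** — segmentation of cumulative records at feed events,
  per-g-VS normalization, smoothed production-rate series and peak
  extraction.
* **Kinetic fitting** — the modified Gompertz model
  `BMP(t) = bBMP exp{−exp[Rmax·e/bBMP·(λ−t) + 1]}` and the first-order
  model, by bounded Levenberg–Marquardt least squares, with RMSE, R²,
  Nash–Sutcliffe efficiency and Gaussian AIC diagnostics.
* **Whole-series ARIMA** — chronological 70/20/10 split, (p,d,q) selection
  by training AIC over a bounded grid, one-step-ahead validation metrics.
* **Dose comparison** — the relative-increase statistic
  `RI = 100 (high − low)/high` for every ordered dose pair.
* **Synthetic experiments** — a seeded generator producing AMPTS-style
  multi-reactor records with known ground truth, for validation and power
  studies.

## Worked example

```r
library(bmpkin)

# theoretical ceiling for the fed substrate
ultimate_potentials(glucose_composition())
#> Buswell-Mueller balance for 'glucose (C6H12O6)'
#>   uBMP   373.3 mL CH4/g-VS
#>   biogas 746.7 mL/g-VS (CH4 fraction 0.500)

# when is the inoculum digested out?
design_plan(first_order_model(3089.74, 0.13))
#> Feeding plan over 60 days
#>   feeds at day 0, 8, 21, 44 ( 2.6, 2.6, 2.6, 2.6 g VS )
#>   inoculum depletion day 36 (35.42 d real)
#>   isolated-substrate phase 4: [44, 60]

# a synthetic 5-dose, triplicate experiment, analysed end to end
ex <- generate_experiment(
  synthetic_spec(replicates = 3, sample_interval_min = 60), seed = 1)
report <- run_pipeline(ex)
report
#> BMP pipeline report: 15 reactors, 5 doses
#>   isolated phase 4 starting day 44
#>  dose_g_per_l n mean_final_phase_bmp mean_total_bmy_ml mean_bbmp mean_rmax
#>             0 3             130.1005          4410.271  129.3599  24.34072
#>             2 3             213.4483          5311.113  212.1713  38.85737
#>             4 3             361.8762          6858.281  366.1847  46.74483
#>             6 3             402.7163          7249.883  404.9304  58.30760
#>             8 3             389.4844          7110.273  387.2097  89.60913
#>   mean_lag    mean_k
#>  0.7466064 0.1993937
#>  0.4383465 0.2215826
#>  0.4726320 0.1328956
#>  0.5040155 0.1566390
#>  0.1137561 0.3341889
```

Reading the table: `mean_final_phase_bmp` is the isolated-phase methane
yield in mL/g-VS (the quantity on which additive effects are sharpest),
`mean_bbmp`/`mean_rmax`/`mean_lag` are the fitted Gompertz plateau
(mL/g-VS), maximum rate (mL/g-VS/d) and lag (d), and `mean_k` the
first-order rate constant (1/d). With three replicates and 5 % replicate
jitter, the 6 and 8 g/L doses overlap — visible above as a slightly higher
plateau at 6 g/L in this draw — which is exactly the kind of sampling noise
the dose-comparison matrix quantifies:

```r
report$relative_increase$phase_bmp
#> Relative increase (%), basis: phase_bmp - rows: higher dose, cols: lower dose
#>       0     2     4    6 8
#> 0  0.00
#> 2 39.05  0.00
#> 4 64.05 41.02  0.00
#> 6 67.69 47.00 10.14  0.0
#> 8 66.60 45.20  7.09 -3.4 0
```

`write_report(report, "out/")` emits the JSON report plus CSV tables, and
`inst/scripts/bmpkin.R` exposes the same stages as shell subcommands
(`ubmp`, `schedule`, `simulate`, `fit-gompertz`, `fit-arima`, `compare`,
`run`).

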