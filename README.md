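# stmrf

Design and evaluation of pulsed saturation-transfer MR fingerprinting
(ST MRF) acquisition schedules, for researchers building CEST and
semisolid-MT quantification protocols on preclinical or clinical scanners.

ST MRF estimates the volume fraction and exchange rate of an exchanging
proton pool, theta = (fs, ksw), by matching measured signal trajectories
against a dictionary of Bloch-McConnell simulations. With very short
schedules (4-8 raw images, under 40 s of scanning) the choice of
per-image saturation powers B1[n] and frequency offsets determines whether
the trajectories of different (fs, ksw) are distinguishable at all. This
package optimizes that choice via the Cramer-Rao bound:

* **Simulator** — multi-pool Bloch-McConnell propagation
  `M(t+dt) = e^{A dt}(M + A^-1 C) - A^-1 C` per piecewise-constant RF
  segment (CW blocks or spin-lock pulse trains), optional Cauchy-Lorentz
  isochromat ensembles for T2*, Lorentzian and super-Lorentzian semisolid
  lineshapes. The hot loop is C++ (RcppArmadillo).
* **Objective** — per dictionary node, Fisher information
  `I(theta) = sigma^-2 J^T J` with the Jacobian from two-point finite
  differences on the (fs, ksw) grid; the loss is the aggregated trace of
  the normalized CRB `I(theta)^-1` (relative-variance normalization by
  default), `L = tr(nCRB)` averaged over interior nodes.
* **Search** — `arg min_phi L(phi)` over the schedule parameters by a
  bound-constrained quasi-Newton local step inside basin-hopping
  (random perturbations + Metropolis acceptance), with a fresh dictionary
  generated for every candidate.
* **Quantification & evaluation** — normalized dot-product matching to
  reconstruct per-pixel (fs, ksw) maps; synthetic vial / two-tissue
  phantoms with known truth; MAPE, NRMSE, SSIM, Pearson r and paired
  t-tests.

## Worked example

Optimize a 4-image continuous-wave L-arginine protocol (16 s of scanning)
from a random start, then quantify a noisy synthetic phantom with it:

```r
library(stmrf)

tpl <- protocol_template("cw7t_larg", n_images = 4)
sch0 <- random_initial_schedule(tpl$schedule, tpl$bounds, seed = 3)
opt <- optimize_schedule(tpl$pools, larg_grid(5, 5), sch0, tpl$bounds,
                         config = optimizer_config(n_hops = 2, seed = 11))
glance(opt)
#> # A tibble: 1 x 4
#>   initial_loss best_loss improvement n_candidates
#>          <dbl>     <dbl>       <dbl>        <int>
#> 1         137.      94.6        42.0            3
opt$best_schedule$b1_uT
#> [1] 0.928 6.000 6.000 5.988
```

The optimizer lowered the CRB loss (the grid-averaged relative variance
bound on any unbiased (fs, ksw) estimator) from 137 to 94.6 and pushed
three of the four powers to the upper bound — a wide, bound-hugging power
spread is the typical signature of CRB-optimized saturation schedules.

```r
phantom <- make_phantom("vial_grid", c(25, 50, 100, 200),
                        c(250, 450, 650, 1050), size = 32, pools = tpl$pools)
grid <- param_grid(3 * 25 / 111e3 * 1:15, seq(50, 1450, by = 100))
dict <- generate_dictionary(tpl$pools, grid, opt$best_schedule)
img <- simulate_acquisition(phantom, opt$best_schedule, sigma = 0.05, seed = 1)
metric_report(phantom, reconstruct_maps(img, dict))
#> # A tibble: 2 x 6
#>   parameter mape_mean_pct mape_sd_pct nrmse  ssim pearson_r
#> 1 fs                245.        231. 0.908 0.346    0.0572
#> 2 ksw                44.6        13.9 0.412 0.736    0.774
```

At this noise level (sigma = 0.05 on a unit-normalized signal) the same
phantom quantified with the *unoptimized* random schedule gives ksw MAPE
56.5 %, NRMSE 0.51, SSIM 0.65 and r 0.72 — the optimized schedule improves
every exchange-rate metric. Four raw images carry little fs information at
this noise regardless of schedule (the large fs MAPE is dominated by the
low-concentration vials); exchange-rate mapping is where optimization
pays, and `autoplot(maps, "ksw")` shows the recovered vials.

A ready-made end-to-end run (optimize, quantify, report, write artifacts)
is `run_pipeline(load_config(list(template = "cw7t_larg")))`, and
`inst/cli/stmrf.R` exposes `optimize` / `run` / `evaluate` subcommands for
shell use.

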