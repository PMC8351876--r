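# sscdyn

Stochastic clone dynamics of transplanted spermatogonial stem cells (SSCs),
for quantitative biologists analyzing lineage-tracing transplantation
assays.

After transplantation into a germ-cell-depleted testis, each labeled SSC
founds a clone that is later scored cross-sectionally: at each harvest
timepoint different hosts are sacrificed and every clone's GFRα1⁺ syncytial
composition (singles A_s, pairs A_pr, chains A_al) and GFRα1⁻ progeny count
are recorded. `sscdyn` provides the forward model for such data and the
machinery to fit it:

* **Clone simulator** — a voter-type lattice model run by an exact Gillespie
  algorithm (compiled core). Each lattice site holds at most one GFRα1⁺
  syncytial unit of length *k*; units divide incompletely (*k* → 2*k*, rate
  λ per unit), fragment (rate (*k*−1)η; each intercellular bridge breaks
  with probability 1/2, displaced fragments land within ± *r* sites and
  differentiate any former occupant into the off-lattice GFRα1⁻ pool *m*),
  die during an initial loss phase (rate γ for *t* < *t*₀), while each
  GFRα1⁻ cell proliferates at rate μ.
* **Ensemble observables** — per-timepoint clone survival *S*(*t*), mean
  persisting clone size ⟨*n*(*t*)⟩, cumulative persisting-size distribution,
  mean progeny ⟨*m*(*t*)⟩, and pooled syncytial composition *r⃗*(*t*).
* **Inference** — CMA-ES minimization of the composite cost
  *C* = ln *R*₁ + ln *R*₂ + ln *R*₃ (composition, relative size, survival
  residuals summed over fit timepoints) over (η, γ, *t*₀) with λ fixed from
  live imaging, a decoupled least-squares stage for μ, and ± 75%
  cost-surface sensitivity scans with ln 2 contour spacing.
* **Synthetic data** — a generator for cross-sectional clone tables from
  known ground truth, for parameter-recovery experiments.
* **Quantification arithmetic** — clone-merger probability
  *p* = 1 − (1 − *a*/*L*)^(*N*−1), labeling efficiencies, and the
  injected-cell budget chain.

## Worked example

Generate a synthetic five-timepoint study at known parameters, summarize it,
and recover the parameters by simulation-based fitting:

```r
library(sscdyn)

truth <- ssc_params(lambda_div = 0.35, eta_frag = 0.25, gamma_loss = 0.3,
                    t0_loss_end = 8.1, mu_prog = 0.35)
design <- study_design(harvest_times = c(2, 6, 10, 14, 20),
                       clones_per_time = 300, truth = truth, seed = 11)
ds <- generate_dataset(design)
ensemble_statistics(ds$table)
#> Ensemble statistics:
#>  timepoint_days n_clones         S mean_n_persisting     mean_m
#>               2      300 1.0000000          1.480000   0.000000
#>               6      300 0.3766667          3.247788   1.263333
#>              10      300 0.2600000          4.833333   6.930000
#>              14      300 0.2500000          6.560000  30.056667
#>              20      300 0.2466667          9.648649 207.756667
#> Syncytial composition (unit fractions):
#>      A_s  A_pr A_al4 A_al8 A_al16+
#>  2 0.700 0.210 0.090 0.000   0.000
#>  6 0.509 0.302 0.142 0.030   0.018
#> 10 0.500 0.298 0.160 0.043   0.000
#> 14 0.434 0.391 0.115 0.055   0.004
#> 20 0.506 0.357 0.114 0.023   0.000
```

Most clones are lost during the initial loss phase (survival drops from 1
to ~0.25 and then stays flat after *t*₀ ≈ 8 days), while the persisting
clones grow and their composition shifts from singles toward longer
syncytia — the characteristic signature of this model class.

```r
fit <- fit_parameters(ds$table, truth,
                      config = fit_config(profile = "reduced",
                                          common_rng = TRUE, seed = 42))
fit
#> Clone-model fit (CMA-ES on C = ln R1 + ln R2 + ln R3)
#>   eta_frag    = 0.2196 /bridge/day
#>   gamma_loss  = 0.3004 /unit/day
#>   t0_loss_end = 8.483 days
#>   mu_prog     = 0.3555 /cell/day
#>   cost C      = -18.38  (R1 0.00872, R2 0.0121, R3 9.82e-05)
#>   evaluations : 500 (0 bound-clipped coordinates)
```

The generating values (η = 0.25, γ = 0.3, *t*₀ = 8.1, μ = 0.35) are
recovered within 12%, 0.2%, 5% and 2% respectively at the reduced
(10³-realization) evaluation budget; the fragmentation rate is the least
constrained parameter, as the sensitivity scan's near-axis-parallel η
contours show.

Closed-form quantification:

```r
p <- merger_probability(n_clusters = 6, mean_extent_a = 1.2,
                        tubule_length_L = 1700)
c(exact = p, reported = report_probability(p))
#>       exact    reported
#> 0.003524433 0.004000000
```

For six clusters of mean extent 1.2 mm on 1,700 mm of tubule, the chance
that a given cluster has merged with another is ~0.35%: scored "clones" at
that density are almost always true clones.

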