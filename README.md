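# mabkin

Kinetic modelling and multistep particle-swarm parameter estimation for
antibody-producing mammalian cell cultures.

Monoclonal-antibody production runs on batch cultures of hybridoma (or
CHO) cells, and process development needs dynamic models whose kinetic
parameters are not directly measurable. `mabkin` implements a
mass-balance model of such a batch: 11 extracellular metabolites coupled
by 9 lumped macroreactions,

    dξ/dt = K φ(ξ),      φ_i = φ_i* · X · ∏_j S_j / (K_Sj,i + S_j),

plus phase-switched viable/dead cell dynamics (growth term dropped after
t_exp = 54 h). Its 23 kinetic parameters (9 rate ceilings φ\*, 12 Monod
half-saturation constants K_S, growth rate μ, death constant k_d) are
estimated from sparse concentration measurements by a multistep particle
swarm optimizer: the problem is split into nine small subproblems
(P1–P9), each fitting one state's balance equation through a one-step
explicit-Euler prediction error on a 0.1-h grid of monotone
cubic-Hermite interpolated measurements, with estimated parameters
frozen forward. A Monte Carlo analysis perturbs the measurements within
their reported standard deviations, re-estimates, excludes outlying
replicates by the interquartile fence, and reports each parameter's
spread as SD% of its mean.

The package bundles the classic 147-h IgG-secreting murine hybridoma
batch data set (7 sampling times, 11 measured variables with standard
deviations) together with three published parameter sets for
comparison, and a synthetic-data generator with an identifiable ground
truth for recovery experiments.

## Worked example

```r
library(mabkin)

## simulate the published multistep-PSO parameter set
p   <- bundled_params("pso")
tab <- load_measurements("bundled")
init <- c(GLC = 3.59, GLN = 2.85, GLU = 0.3, ASN = 0.46, ASP = 0.27,
          LAC = 0.51, ALA = 0.33, PRO = 0.30, MAb = 0.34e-4,
          BM = 2.01, NH3 = 0, X = 0.09, Xd = 0.02)
tr <- simulate_batch(init, p)
tr[nrow(tr), c("GLN", "BM", "X")]
#>        GLN         BM          X
#> 0.04719611 18.2866800 0.04023768
```

Glutamine is exhausted by the end of the batch (0.047 mM), biomass
plateaus near 18 mM, and the viable-cell density has collapsed from its
mid-batch peak (`max(tr[, "X"])` ≈ 0.82 × 10⁶ cells/mL at 54 h) —
the depletion/peak pattern of the measured data.

```r
## estimate all 23 parameters from the bundled measurements
## (reduced 50-particle / 100-iteration profile; ~10 s)
fit <- multistep_estimate(tab, cfg = swarm_config(profile = "reduced"),
                          seed = 1)
round(c(mu = fit$params$mu, kd = fit$params$kd), 4)
#>     mu     kd
#> 0.0451 0.0626
```

The growth and death constants land close to the published estimates
(0.043, 0.067); most half-saturation constants, by contrast, are far
above the observed substrate ranges and only their ratios with the
paired rate ceilings are determined — the Monte Carlo analysis
(`run_monte_carlo()`) quantifies exactly which parameters the data do
and do not pin down.

```r
## recovery experiment on synthetic data with identifiable parameters
spec <- identifiable_preset(noise_mode = "cv", cv = 0.01, seed = 1)
synth <- generate_measurements(spec)
res <- multistep_estimate(synth, cfg = swarm_config(profile = "reduced"),
                          seed = 1)
res$params$mu                     # truth: 0.043
#> [1] 0.04334
```

Shell entry points wrapping the same functions live in
`inst/scripts/mabkin.R` (`simulate`, `fit`, `montecarlo`, `synth`
subcommands with YAML configs).

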