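# microloop

Deterministic modelling of a reduced marine microbial loop: a diatom and a
heterotrophic bacterium in co-culture, coupled only through dissolved
organic matter (DOM). The package is aimed at microbial ecologists who want
to turn sparse, replicated cell-count time series (weekly plate counts and
haemocytometer counts over a few weeks) into estimates of the rates that
govern a phototroph-heterotroph association — above all the exudation rate,
i.e. how fast living phytoplankton cells feed carbon to their satellite
bacteria.

## The model

Four state variables — bacterial concentration $B$ (CFU ml⁻¹), diatom
concentration $D$ (cells ml⁻¹), and two DOM pools in bacterial cell
equivalents ml⁻¹: exudates $DOM_E$ and dead-biomass detritus $DOM_B$ —
evolve as

$$
\dot B = (\mu_B - \delta_B)B, \qquad
\dot D = (\mu_D - \delta_D - \lambda)D,
$$
$$
\dot{DOM_E} = \lambda D - \mu_{B,E} B - \delta_{DOM_E}\,DOM_E, \qquad
\dot{DOM_B} = \delta_D D - \mu_{B,B} B - \delta_{DOM_B}\,DOM_B,
$$

with Verhulst diatom growth $\mu_D = \nu_{\mu_D}(1 - D/CC_D)$,
growth-damped death rates $\delta_D = \nu_{\delta_D}/(1+\mu_D)$ and
$\delta_B = \nu_{\delta_B}/(1+\mu_B)$, and self-saturating Monod-limited
bacterial growth solved exactly as the nonnegative root of
$\mu_B(1+\mu_B) = \nu_{\mu_B}\bigl(\frac{DOM_E}{DOM_E+K_{DOM_E}} +
\frac{DOM_B}{DOM_B+K_{DOM_B}}\bigr)$, split into per-pool components
$\mu_{B,E} + \mu_{B,B} = \mu_B$. Integration uses an adaptive
Dormand–Prince RK4(5) scheme in compiled code; parameter estimation
minimizes a (log-scale) squared deviation with a Nelder–Mead simplex whose
vertex comparisons are annealed with Boltzmann noise, cooled geometrically.
The methods vignette (`vignettes/coculture-model.Rmd`) derives every choice,
including how the model's structural ambiguities are resolved and why
the Monod pair $(\nu_{\mu_B}, K_{DOM_E})$ is only jointly identified by a
5-time-point design.

## Worked example

```r
library(microloop)

params <- coculture_params()            # reference parameterization
traj <- integrate_coculture(params, coculture_state(), times = 0:28)
print(traj)
#> Co-culture trajectory: 29 time points over 28 days
#>  time       B       D  DOM_E  DOM_B
#>     0  100000  200000      0      0
#>     6   57120  509100  78750  63150
#>    11  110800 1079000 201300 161400
#>    17  708600 2471000 221600 175500
#>    22 1543000 4419000 116800  96210
#>    28 2777000 7326000 106200  90600
```

The bacterium first declines (no carbon yet), doubles its inoculum only at
day 14, then rides the accumulating exudate pool; the diatom rises
near-linearly towards ~10⁷ cells ml⁻¹ — the qualitative shape of the real
co-culture. Generate a synthetic experiment from this "truth" and refit the
bacterial kinetics:

```r
truth <- ground_truth(params)
syn <- generate_observations(truth, synthetic_design(noise_cv = 0.05, seed = 1))
cfg <- fit_config(free = c("nu_mu_B", "lam", "K_DOME"), seed = 1)
fit <- fit_coculture(syn$observations, cfg, params = params)
summary(fit)
#> Parameter estimates:
#>  parameter   estimate   start at_bound
#>    nu_mu_B 2.3161e+00 2.5e+00    FALSE
#>        lam 5.0505e-02 5.0e-02    FALSE
#>     K_DOME 1.2533e+06 1.5e+06    FALSE
#>
#> Goodness of fit (squared Pearson R2, per-time replicate means):
#>  series     R2   p_value n
#>       B 0.9992 9.901e-06 5
#>       D 0.9997 2.574e-06 5
#>   ratio 0.9984 2.752e-05 5
#>
#> Objective: 0.0110579 | evaluations: 18508 | converged: TRUE | seed: 1
```

The exudation rate comes back within 1%; the Monod pair lands on the ridge
discussed in the vignette (here −7% and −16%). R² is reported for both
species and their cell-count ratio. How much does the bacterium depend on
actively released photosynthates? Sweep λ and run long enough to approach
steady state:

```r
sweep_exudation(params, fractions = c(0, 0.5, 1), horizon = 100)
#> Parameter sweep over lam ( 3 levels )
#>  level   lam final_B  final_D
#>    0.0 0.000 4513000 16180000
#>    0.5 0.025 5978000 14270000
#>    1.0 0.050 6906000 12350000
```

Final bacterial density falls as exudation is throttled (and the diatom,
spared the exudation cost, climbs). `sweep_initial_dom()` asks the mirror
question — how a head start of dissolved carbon shortens the two-week
bacterial lag.

A thin command-line wrapper (`inst/cli/coculture`) exposes the same
pipeline as `simulate`, `fit`, `sweep`, `synth` and `gof` subcommands over
delimited observation tables and flat JSON config files; every run writes a
manifest recording config, paths, seed and package version.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's end-to-end pipeline from scratch: the baseline
28-day simulation, a synthetic-data refit with goodness-of-fit report, the
exudation-rate sweep (0–100% of baseline λ over 100 days) and the
initial-DOM sweep (1–5× over 28 days), printing each result and writing the
JSON summary to `--out`.
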