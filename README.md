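# beedemog

Seasonal elasticity analysis of honeybee colony demography.

Honeybee workers show extreme plasticity in aging: summer bees live
2–6 weeks while winter bees survive for months. Because workers barely
reproduce themselves, the selective pressure on worker senescence acts
through colony performance, and threats to colony health (Varroa,
pesticides, nutrition stress) are usually measured on individuals.
`beedemog` is for evolutionary ecologists and bee-health modellers who
need to translate changes in *individual* worker mortality into
effects on *colony* growth, season by season.

## The model

The colony is an age-structured Leslie matrix over brood (ages 1–21),
nurses (1–120) and foragers (1–19). Brood production is food-limited:
each forager contributes $r = p/c$ new brood per day ($p$ food
provisioned per forager-day, $c$ food per brood-day). Brood survive
daily with probability $s_b$ and emerge as nurses; nurses survive with
Gompertz–Makeham probability $s_{n,i} = 1 - (\alpha_n e^{\beta_n i} +
\gamma_n)$ and become foragers with daily probability $g$; foragers
survive with the analogous $s_{f,i}$. The dominant eigenvalue
$\lambda$ of the resulting $160\times160$ matrix is the per-day colony
growth factor, and the selective pressure on a mortality parameter $x$
is its elasticity

$$ e(x) = \frac{\Delta\lambda}{\Delta x}\,\frac{x}{\lambda}, $$

computed by central-difference perturbation and cross-checked against
the analytic eigenvector-sensitivity identity
$\partial\lambda/\partial a_{ij} = v_i w_j / \langle v, w \rangle$.

Three bundled scenarios (summer, spring/fall, winter) encode the
seasonal contrasts in food availability, extrinsic mortality and
nurse-to-forager transition; a recursion simulator provides an
independent oracle for $\lambda$, and a seeded ensemble sampler checks
that the qualitative conclusions survive parameter uncertainty. See
`vignettes/colony-demography.Rmd` for the full methods account,
including how the default values were calibrated.

## Worked example

```r
library(beedemog)

scen <- default_scenarios()
sapply(scen, function(s) expected_adult_lifespan(s$params))
#>      summer spring_fall      winter
#>    16.64186    18.69746    72.57294

M <- build_leslie_matrix(scen$winter$params)
eigen_analysis(M)
#> dominant eigenvalue (daily colony growth rate): 0.97722232

print(ordering_report(season_comparison(scen)))
#> [PASS] |e(gamma_n)|: summer >= spring_fall > winter, summer ~ spring_fall
#>         summer 2.798e-03  spring_fall 2.287e-03  winter 5.606e-04
#> [PASS] |e(alpha_n)|: winter above both other seasons
#>         summer 7.370e-05  spring_fall 7.089e-05  winter 1.685e-04
#> [PASS] |e(beta_n)|: winter above both other seasons
#>         summer 3.957e-06  spring_fall 3.820e-06  winter 3.225e-05
#> [PASS] |e(gamma_f)|: summer > spring_fall > winter
#>         summer 2.513e-02  spring_fall 2.111e-02  winter 1.318e-04
#> [PASS] |e(alpha_f)|: winter > spring_fall > summer
#>         summer 4.009e-04  spring_fall 8.399e-04  winter 1.234e-03
#> [PASS] |e(beta_f)|: winter > spring_fall > summer, spring_fall nearer summer
#>         summer 4.570e-04  spring_fall 1.434e-03  winter 3.028e-03
#> all 6 orderings hold: TRUE
```

Reading the numbers: adult workers live 2.4 weeks under summer
conditions and 10.4 weeks under winter conditions; the winter colony
shrinks slowly ($\lambda = 0.977$/day) while summer and spring
colonies grow. The orderings say the colony is most sensitive to
age-independent (extrinsic) worker mortality in summer, but most
sensitive to age-dependent (senescent) mortality in winter — seasonal
selection that matches the observed pattern of slow-aging winter bees.

## The analysis scripts

The analyses are numbered scripts over the package API,
each writing its tables under `results/`:

```sh
Rscript analysis/01_scenarios.R           # parameter table, lambda, lifespans
Rscript analysis/02_growth_rates.R        # eigenvalue vs simulator cross-check
Rscript analysis/03_season_elasticity.R   # seasonal elasticity tables + figures
Rscript analysis/04_brood_sweep.R         # elasticities vs brood survival
Rscript analysis/05_ensemble_robustness.R # orderings under 10% parameter spread
```

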