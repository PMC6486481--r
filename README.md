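# golgisim

Stochastic simulation and Bayesian fitting of Golgi N-glycan processing.

N-linked glycans leave the ER as high-mannose precursors (Man8, Man9,
Man9Glc) and are remodelled during transit through the Golgi stack by
competing glycosidases and glycosyltransferases.  Because there is no
template and residence time is limited, the output is a heterogeneous
mixture whose composition encodes the levels and cisternal localization of
the processing enzymes.  `golgisim` is for researchers who want to turn a
measured glycan profile (relative abundances of compositions such as
`Fuc1Hex5HexNAc4`, e.g. from MALDI-MS of permethylated glycans) into
quantitative statements about that machinery: which cisterna an enzyme
acts in, how its effective rate changes under drug treatment, knockout or
differentiation, and which reaction fluxes reroute as a result.

## The model in brief

A glycan is a rooted residue tree, round-trippable to a linear notation
(`GlcNAc4.1GlcNAc4.1Man(3.1Man:)_m6.1Man(3.1Man:)_m6.1Man:@` is
Man5GlcNAc2).  Enzymes are substrate-pattern → substitution rules; in
cisterna *c* a matching rule instance *i* of enzyme *e* has propensity
*r<sub>i</sub> = k<sub>e,c</sub> · s<sub>i</sub>*, with *k* the effective
rate (enzyme level × donor availability × catalysis, min⁻¹) and *s* a
substrate scale factor.  Each of *n* = 10,000 independent glycans runs a
Gillespie simulation per cisterna: waiting times are Exponential(mean
1/*R*) with *R* = Σ*r<sub>i</sub>*, reaction *i* fires with probability
*r<sub>i</sub>*/*R*, and the glycan exits the cisterna when the clock
would cross the residence time (10 min default).  Final structures are
collated by composition into a percent profile (entries < 0.1% dropped).

Effective rates are fitted to an observed profile by rejection ABC.  The
discrepancy score is

score = Σᵢ (semᵢ − |obsᵢ − simᵢ|)²,  with zero contribution where |obsᵢ − simᵢ| < semᵢ,

so a simulation inside the SEM band everywhere scores 0.  Parameter draws
come from localization priors (log-normal in an enzyme's home cisterna,
exponential decay elsewhere); the acceptance threshold shrinks by 10%
whenever the acceptance rate over the last 1,000 proposals exceeds 7%,
then holds at a final threshold until the target number of draws is
accepted.  Gelman-Rubin statistics and Mann-Whitney prior-shift tests
diagnose the result, and reaction flux maps (event counts on
substrate → product edges) expose the pathway rearrangements behind a
profile change.

## Worked example

Parse a printed notation string, generate a synthetic "observed" profile
from a known ground truth, and fit it:

```r
library(golgisim)

glycan_parse("GlcNAc4.1GlcNAc4.1Man(3.1Man2.1GlcNAc4.1Gal:)_m6.1Man2.1GlcNAc4.1Gal6.2Sia:@")
#> <glycan> GlcNAc4.1GlcNAc4.1Man(3.1Man2.1GlcNAc4.1Gal:)_m6.1Man2.1GlcNAc4.1Gal6.2Sia:@
#>   composition: NeuAc1Hex5HexNAc4   class: complex

sc  <- make_scenario("recovery-3c5e", seed = 42, n_glycans = 2000)
obs <- synth_observed(sc)        # triplicate SSA profile with SEMs
head(obs, 4)
#>  composition abundance_pct sem_pct
#>  Hex3HexNAc3        0.5333  0.1740
#>  Hex4HexNAc3       20.4833  0.3114
#>  Hex5HexNAc2       13.5667  0.5044
#>  Hex5HexNAc3        8.5167  0.6870

fit <- golgi_abc(obs, sc$ground_truth, scenario_priors(sc),
                 ruleset = scenario_ruleset(sc), n_glycans = 2000,
                 target_accepted = 500, n_chains = 4, seed = 7)
fit
#> Golgi effective-rate fit (rejection ABC)
#>   accepted draws: 500 over 4 chains (8835 proposals)
#>   threshold: 557.6 -> 108
#>   parameters: 15

summary(fit)[c(1, 5, 8, 12, 15), ]
#>        param  mean     sd  lower upper  rhat  shift_p shifted
#>      MAN1.c1 0.374 0.0754 0.2410 0.488 0.996 0.000481    TRUE
#>     MGAT1.c2 0.200 0.1460 0.0792 0.422 1.000 0.143000   FALSE
#>      MAN2.c2 0.317 0.2100 0.1180 0.737 0.997 0.001830    TRUE
#>      GalT.c3 0.466 0.4550 0.1120 1.250 0.998 0.037800    TRUE
#>  OMquench.c3 0.104 0.1040 0.0218 0.264 0.997 0.294000   FALSE
```

The summary rows read: posterior mean and SD of each effective rate
(min⁻¹), its central 90% credible interval, the Gelman-Rubin statistic
across the 4 chains (≈1 means converged), and the Mann-Whitney p-value
for a prior-to-posterior shift.  Here the fit recovers the ground truth —
e.g. MAN1 in cisterna 1 was simulated at 0.40 and is estimated at 0.374
with interval [0.24, 0.49] — and flags the parameters the data actually
moved.  `coef(fit)` returns the posterior means, `simulate(fit)` replays
triplicate profiles at those means, `residuals(fit)` gives per-key
observed-minus-fitted abundances, and `plot(fit)` overlays prior and
posterior densities.

Flux analysis works from any simulation:

```r
sim <- simulate_profile(scenario_model(make_scenario("complex-4c")), 10000, seed = 1)
top_reactions(sim$flux, "FUT8", k = 6)                  # busiest fucosylation steps
galt_titration(scenario_model(make_scenario("complex-4c")),
               c(0.25, 0.5, 1, 2, 4), 10000, seed = 1)  # branching vs GalT activity
```

A command-line front end with verbs `synth`, `simulate`, `fit`,
`diagnose`, `flux` and `sweep` is installed at
`system.file("cli", "golgisim.R", package = "golgisim")`.

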