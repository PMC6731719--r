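# malaisecatch

Catch modelling for Malaise-trap insect surveys.

Malaise traps — tent-like interception traps serviced every couple of
weeks — are the workhorse of tropical insect inventories, but their
catches are usually mined only for taxonomy. `malaisecatch` implements
the full ecological analysis behind a year-long, 34-trap survey of the
parasitoid wasp subfamily Rhyssinae in Kibale National Park, Uganda,
and is aimed at ecologists who want to ask of their own trap data:
*when* do these insects fly, and *where*?

For each species the expected catch of one trap-service interval is

```
E[Catch] = days · exp(a1 + a2·date + a3·rain + a4·deadwood + a_foresttype)
```

with negative-binomial (NB2) errors (`Var = μ + μ²/θ`); `days` is the
sampling effort (a fixed offset), `date` counts days to the interval
midpoint, `rain` is mean daily rainfall over the interval, `deadwood`
is `Σ dbh²/distance` over clearly decaying trees in two trap-centred
transects, and forest type is a five-level successional factor with
primary forest as the reference. The significance of each variable —
per species and for the assemblage as a whole (the *sum* of
species-wise likelihood ratios) — is assessed against a null
distribution built by resampling trap sites, which respects within-site
correlation; forest types are also contrasted pairwise, and no
multiple-testing adjustment is applied (a deliberate choice, stated on
every report). A synthetic-campaign generator reproduces the sampling
structure of the 2014–2015 field study so the entire pipeline is
testable without any download.

## A worked example

Simulate a default campaign, build the design, fit one species and test
the dead-wood effect:

```r
library(malaisecatch)

scen   <- make_default_scenario(seed = 1)
d      <- filter_samples(simulate_dataset(scen))
design <- assemble_design(d)

fit_species(design, "Epirhyssa uelensis")
#> NB2 catch model for Epirhyssa uelensis (n = 287 individuals)
#>   theta = 0.695, loglik = -465.511, converged = TRUE
#> intercept      date      rain  deadwood     swamp disturbed  clearcut      farm
#>   -4.2842    0.0055   -0.3352    2.4994   -1.4211   -0.4671   -0.8092  -15.0000
#>   separated: farm

term_test(design, "deadwood", B = 199, seed = 1)
#> LR resampling test: deadwood (B = 199, scheme = residual, blocks = site)
#>                species     LR     p
#>  Epirhyssa ghesquierei 22.355 0.005
#>      Epirhyssa johanna  0.317 0.460
#>    Epirhyssa overlaeti 66.230 0.005
#>       Epirhyssa quagga 12.219 0.005
#>  Epirhyssa tombeaodiba  0.548 0.410
#>     Epirhyssa uelensis  7.721 0.025
#>   summed LR = 109.390, overall p = 0.005
#>   (p-values are not adjusted for multiple testing)
```

Reading the output: the species was generated with a dead-wood
coefficient of 2.31 and the fit recovers 2.50, so a trap next to a
large decaying log (score 0.27, the best trap of the field study)
catches `exp(2.50 × 0.27) ≈ 2.0` times what a log-free trap catches;
the date coefficient 0.0055 means catches roughly double every 126
days; farmland produced no catches at all, so its dummy is pinned at
the −15 cap and flagged `separated` rather than reported as a real
estimate. The assemblage-level dead-wood test is significant at the
resampling floor (p = 1/200), driven by the four well-sampled species;
the two species with a handful of individuals contribute little and
are flagged low-n in reports.

Relative catches by forest type (primary standardised to 1; 0 marks a
level flagged as not estimable):

```r
round(relative_catch(fit_all_species(design)), 3)
#>                       primary swamp disturbed clearcut  farm
#> Epirhyssa ghesquierei       1 2.101     0.526    1.007 0.000
#> Epirhyssa johanna           1 0.532     0.000    0.083 0.029
#> Epirhyssa overlaeti         1 1.701     0.278    0.126 0.000
#> Epirhyssa quagga            1 1.254     0.600    0.822 0.000
#> Epirhyssa tombeaodiba       1 1.134     1.119    0.000 0.000
#> Epirhyssa uelensis          1 0.241     0.627    0.445 0.000
```

The same pipeline is scriptable from the shell via
`inst/cli/malaisecatch` (subcommands `simulate | covariates | fit |
test | pairwise | predict | report`), each stage writing CSV artefacts
plus a JSON provenance record with the resolved configuration, seed
and input checksums.

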