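# seamountEBSA

Seamounts — submarine mountains rising more than 100 m from the seafloor
without breaking the surface — are biodiversity hotspots and prime
candidates for open-ocean protection under the Convention on Biological
Diversity (CBD) criteria for Ecologically or Biologically Significant
Areas (EBSA). Yet most seamounts are poorly surveyed, so any practical
evaluation has to work from presence/absence evidence and be explicit
about how much of that evidence is missing or weak.

`seamountEBSA` implements a complete desk-scale evaluation framework for
individual seamounts, aimed at marine conservation scientists and managers
prioritising sites:

- **EBSA likelihood score.** Ten weighted indicator slots (hydrothermal
  vents, macrophytes, cold-water corals, sponge aggregations, aggregating
  deep-sea fishes, threatened bottom fish, two OR-pair pelagic slots, a
  naturalness flag, and summit depth above 800 m) proxy the seven CBD
  criteria. With `W` the sum of weights of the indicators present and
  `W_max = 21` the maximum achievable,

  `S = 1 + 4 W / W_max`, with `S ≤ 3` categorised *low* and `S > 3` *high*.

- **Threat score.** Nine human activities (eight fishing gears plus
  seafloor mineral extraction) are rated 1–5 against five ecological
  groups in an impact matrix `M`. For the activities `A` present on a
  seamount,

  `TS = mean_g ( max_{a ∈ A} M[a, g] )`,

  categorised *none* (TS = 1), *low* (1 < TS ≤ 3) or *high* (TS > 3).

- **Data-uncertainty index.** `U = mean(DQ) + DD`, the mean evidence-grade
  weight over scored observations (high 0, medium 0.5, low 1) plus the
  fraction of slots with no data, drawn as symmetric error bars `S ± U`.

- **Conservation portfolio.** Crossing the two categories classifies each
  seamount into one of four cells (e.g. *high EBSA–low threat* = pristine
  and valuable), the basis of the quadrant plot used to compare sites.

- **Impact-matrix reconstruction.** Published applications report threat
  scores and activity sets but not always the rating matrix behind them.
  `fit_impact_matrix()` reconstructs a canonical matrix from such
  (activity set, score) pairs by backtracking search over the integer
  ratings (compiled in C++), with an explicit tie-break: minimal total
  severity, then lexicographic order. The packaged default matrix is the
  canonical solution for the eight case-study constraints.

- **Dummy-seamount simulator.** `simulate_seamounts()` generates random
  indicator/threat configurations to probe how the framework spreads
  records over the portfolio, with an exact enumeration reference
  (`ebsa_high_probability()`) for the high-EBSA fraction.

Eight fully transcribed case-study seamounts ship with the package:
Sedlo, Condor, Rosemary, Anton Dohrn, Josephine, Gorringe, Bowie and
Cobb.

## Worked example

```r
library(seamountEBSA)

assess_seamounts(case_study_seamounts())
#> Seamount assessment: 8 seamount(s)
#> # A tibble: 8 × 8
#>   seamount    ebsa_score ebsa_category ebsa_uncertainty threat_score
#>   <chr>            <dbl> <chr>                    <dbl>        <dbl>
#> 1 Anton Dohrn       3.29 high                      0.58          3.6
#> 2 Bowie             3.1  high                      0.45          2.4
#> 3 Cobb              3.1  high                      0.49          2.6
#> 4 Condor            3.48 high                      0.35          3.6
#> 5 Gorringe          3.86 high                      0.58          4.6
#> 6 Josephine         3.29 high                      0.7           5
#> 7 Rosemary          2.52 low                       0.59          5
#> 8 Sedlo             3.86 high                      0.25          2.6
#> # ℹ 3 more variables: threat_category <chr>, threat_uncertainty <dbl>,
#> #   portfolio <fct>
```

(The call warns that Sedlo is recorded as natural while a pelagic
longline fishery is present — an inconsistency in the source data that is
preserved, flagged, and not fatal.)

Reading the rows: Sedlo scores 3.86 on the EBSA scale (high likelihood)
with low uncertainty (0.25) and a low threat score of 2.60 driven solely
by pelagic longlining — a *high EBSA–low threat* site, i.e. a pristine
candidate for protection. Rosemary is the only *low* EBSA site (2.52) but
carries six active gears (threat 5.00): *low EBSA–high threat*. Josephine
is nominally high (3.29) but its uncertainty of 0.70 spans 2.59–3.99,
i.e. the evidence cannot yet settle its category.

Plots and exports:

```r
a <- assess_seamounts(case_study_seamounts())
plot_portfolio(a)                      # quadrant scatter with error bars
plot_radar(case_study_seamounts())     # per-seamount component profiles
portfolio_plot_data(a)                 # the scatter data as a tibble
```

Rebuild the impact matrix from score constraints:

```r
fit <- fit_impact_matrix(case_study_constraints(),
                         prior = list(mineral_extraction = c(5, 5, 4, 2, 1)))
glance(fit)
#> # A tibble: 1 × 5
#>   n_constraints n_fitted_activities n_prior_activities fitted_rating_sum
#>           <int>               <int>              <int>             <int>
#> 1             9                   8                  1                69
#> # ℹ 1 more variable: max_constraint_error <dbl>
```

A command-line wrapper with `score`, `simulate`, `fit-matrix` and
`report` subcommands is installed at
`system.file("cli", "seamount-ebsa.R", package = "seamountEBSA")`.

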