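---
title: "Methods: scoring seamounts against the EBSA criteria"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring seamounts against the EBSA criteria}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seamountEBSA)
```

`seamountEBSA` evaluates individual seamounts on two axes — how likely a
seamount is to qualify as an Ecologically or Biologically Significant
Area (EBSA) under the CBD criteria, and how threatened it is by the
fishing and mining activities present — and attaches an explicit
evidence-based uncertainty to both. This vignette explains the model,
its assumptions, the tunable parameters, and the design choices made
where the published framework left matters open.

## The EBSA likelihood score

A seamount record scores ten indicator slots, each *present*, *absent*
or *data deficient* (DD). Each indicator carries an integer weight equal
to the number of CBD criteria it speaks to (kept as metadata in
`ebsa_indicators()$criteria`): the four benthic habitat indicators weigh
3, aggregating deep-sea fishes 2, threatened bottom fish 1, naturalness
and summit depth 1. Two slots are OR-pairs — air-breathing visitors and
visiting large pelagics are scored either as their threatened variant
(weight 2, when red-listed species are involved) or their plain variant
(weight 1), never both.

With $W$ the sum of the weights present and $W_{max} = 21$ the maximum
achievable (threatened variant of each pair), the score is the linear
map of $W$ onto a 1–5 scale:

$$S = 1 + 4\,W / W_{max}.$$

Two modelling commitments matter here:

* **The denominator is fixed at $W_{max}$.** It does not shrink when a
  plain pair variant is scored or when slots are data deficient. The
  score answers "how much EBSA evidence is on the table", on a scale
  anchored by the best possible record; missing evidence is *not*
  silently forgiven but carried by the uncertainty index. This is also
  the only reading that reproduces all eight published case-study scores
  simultaneously (Condor's 3.48 with a plain variant, Rosemary's 2.52
  with three DD slots).
* **Data deficiency contributes zero to the numerator.** A likelihood
  score given evidence, not an imputation; again matched by the
  published values for the three heavily data-deficient Atlantic
  seamounts.

Since $W$ is an integer, the published category boundary $S \le 3$ is
equivalent to $W \le 10$: `high` means $W \ge 11$. Tests verify this
equivalence, and the score bounds $1 \le S \le 5$, over every one of the
$2^8 \times 3^2 = 2304$ indicator configurations (eight plain slots
$\times$ two three-state pairs).

Custom catalogs (other weights or slots) are accepted; the denominator
is then that catalog's own maximum achievable weight.

## The threat score

Nine activities are considered: bottom gillnet, hook and line, bottom
and pelagic longline, pots and traps, purse seine, bottom and midwater
trawl, and seafloor mineral extraction. An impact matrix rates each
activity against five ecological groups (physical habitat, corals and
sponges, groundfish, large pelagics, air-breathing visitors) on an
integer 1 (very low) to 5 (very high) scale. The threat score is the
mean over groups of the worst impact among the activities present:

$$TS = \tfrac{1}{5}\sum_g \max_{a \in A} M[a,g].$$

A group with no impacting activity contributes 1 — not 0 — so "no
activity" and "uniformly very-low impact" coincide at the published
score floor of $TS = 1$. Data-deficient activities are treated as absent
for scoring (they enter the uncertainty index instead); this is what the
published case-study scores require (Cobb, with four DD activities,
scores 2.60 from its present gears alone). Categories: `none`
($TS = 1$), `low` ($1 < TS \le 3$), `high` ($TS > 3$).

## Reconstructing the impact matrix

The per-cell ratings behind published threat scores are not always
available; what is available is a set of (activity set, threat score)
pairs. Each pair pins the sum of per-group maxima over its activity set
to $5 \times TS$. `fit_impact_matrix()` treats the 45 cells as integer
unknowns and searches by depth-first backtracking with constraint
propagation:

* per-constraint bounds — current maxima (`lo`) versus attainable maxima
  (`hi`, 5 while unassigned member cells remain) — prune any branch whose
  maxima sums cannot reach the target;
* a *deficit bound* computes, by exact enumeration of group subsets, the
  cheapest additional severity a constraint still needs, and prunes
  against the running sum budget;
* the system is underdetermined (45 unknowns, a handful of equalities),
  so the returned solution is made canonical by an explicit tie-break:
  **minimal total rating sum, then lexicographically smallest** in
  activity-major cell order — the least severe matrix consistent with
  the evidence. The search first proves the minimal sum by
  branch-and-bound (visiting activities in an order that completes small
  constraints early), then returns the first solution of a lexicographic
  pass at that sum. The inner search is compiled (C++) because the
  40-cell integer space is far too large for interpreted backtracking.

Correctness of the solver is tested against exhaustive enumeration of
*all* matrices on reduced instances (3 activities × 3 groups, ratings
1–3, \(3^9\) matrices), comparing both feasibility and the canonical
choice.

Activities appearing in no constraint are unidentifiable; their rows
come from a documented prior. In the packaged default, mineral
extraction (present on none of the case studies) is priored at
(5, 5, 4, 2, 1): crust and sulphide extraction removes substrate and the
fauna attached to it, displaces groundfish, and has modest direct effect
on pelagic visitors. The default matrix — the canonical solver output for
the eight case-study constraints plus the standalone pelagic-longline
score of 2.6 — ships as an editable CSV (`extdata/default_impact_matrix.csv`)
and is validated on load; users with a region-specific elicitation can
substitute their own. Note the canonical matrix is one member of the
feasible set, *not* necessarily the original expert elicitation: only
its score behaviour on the constrained activity sets is identified.

## The data-uncertainty index

Each scored observation carries an evidence grade: high (weight 0),
medium (0.5) or low (1). For each domain (indicators; threats)
independently,

$$U = \overline{DQ} + DD,$$

the mean grade weight over scored slots plus the fraction of slots with
no data (denominator 10 for indicators — an OR-pair is one slot — and 9
for threats). $U = 0$ means everything scored at high quality; a fully
data-deficient record attains the limiting maximum $U = 2$ because the
mean over an empty scored set is defined as 1, the worst grade. The
index is bookkeeping, not a variance: error bars $S \pm U$ are drawn
symmetric and deliberately unclipped, so an uncertain score near the
scale end visibly spills across the category boundary.

One published value is internally inconsistent at the second decimal:
Josephine's threat uncertainty computes to $5/6 + 1/3 = 1.1\overline{6}$
but is printed as 1.16 (the authors presumably rounded the components
before summing). The package does not imitate that; comparisons use a
0.01 tolerance.

## Portfolio classification and the dummy-seamount simulator

Crossing the EBSA category with the threat category yields four
portfolio cells; `none` maps to the low-threat side, since the portfolio
contrasts pristine against impacted sites. All four cells are reachable
and tests construct records landing in each.

`simulate_seamounts()` emulates the published robustness exercise:
records with every indicator slot independently present with probability
`p_indicator` (default 0.5), present pairs threatened with probability
`p_threatened` (0.5), activities present with probability `p_threat`
(0.5), all graded high quality, none data deficient. The defaults are
the neutral choice for a methodology probe — every configuration equally
likely — because the original exercise does not state its randomisation
law. For the same reason the original cell percentages (5.1 / 3.6 /
36.2 / 55.1) are quoted here as the original result only and are **not**
reproduction targets: under the neutral law the exact probability of a
high EBSA category is `ebsa_high_probability(0.5, 0.5)` $\approx 0.444$,
already incompatible with the original 60.2% high fraction, so the
original generator must have been biased toward presence. What *is*
checked is internal consistency: simulated proportions converge (within
three standard errors at the test's $n = 1500$) on the exact probability
computed by convolving the per-slot weight distributions, itself
verified against brute-force enumeration of all 2304 configurations.

What the simulator does not emulate about real data: spatial and
temporal structure, correlated indicators (coral and sponge presence
co-vary in reality), uncertainty patterns (real records are graded and
gappy), and any realistic prevalence of indicators. Passing simulation
tests therefore shows the scoring machinery is correct and
well-behaved, not that the framework is validated against nature.

## Numerical conventions and edge cases

* Display rounding is half-up to 2 decimals (`round_half_up()`), the
  convention of the published tables; `base::round()`'s half-to-even
  would print some values differently. An ulp-scale epsilon keeps
  decimally exact halves (0.575) rounding up despite binary storage.
  Categories and error bounds are computed from unrounded values, which
  are retained in `*_raw` columns.
* Score constraints must have $5 \times TS$ integer (within 0.005) in
  [5, 25]; an empty activity set is feasible only at $TS = 1$.
* Infeasible constraint systems raise a typed error naming an
  unsatisfiable subset (found by testing singletons, then growing the
  set).
* Validation treats a structurally broken record (missing slots, both
  pair members scored, grades on DD observations) as an error, but a
  naturalness flag coexisting with recorded fishing as a warning only —
  one published case study (Sedlo) has exactly that inconsistency and is
  preserved verbatim.

## Problem sizes used by the test suite

Exhaustive EBSA enumeration covers all 2304 indicator configurations;
threat monotonicity uses 20 random matrices and records; the solver
oracle enumerates $3^9$ matrices on 25 random reduced instances; the
simulation check uses 1500 dummy seamounts at a fixed seed. These sizes
make the checks exact or tight while keeping the default suite quick on
a single CPU.

## Known limitations

* The framework is evidence-in, score-out: no effort, catch, bycatch or
  gear-footprint modelling, no climate-change or pollution terms, and no
  endemism indicator (all outside the published framework's scope).
* The reconstructed impact matrix is canonical, not historical; off-
  constraint activity sets may score differently under the original
  elicitation than under the reconstruction.
* Scores for different seamounts are comparable only under the same
  catalog and matrix; the package does not attempt cross-catalog
  normalisation.
* The uncertainty index is additive bookkeeping; it has no probabilistic
  interpretation and the error bars are not confidence intervals.
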