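---
title: "Models and methods behind reinfiso"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind reinfiso}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reinfiso)
```

reinfiso analyzes two kinds of mate-choice data for the behavioral
signature of reinforcement — stronger conspecific preference where two
species co-occur. This vignette explains the statistics it computes, the
generative model behind its synthetic trials, the numerical choices made
where several were defensible, and what the package's tests do and do not
establish about real data.

## The two isolation statistics

**Strength of preference.** For a dichotomous trial with conspecific and
heterospecific association times $T_C$ and $T_H$ (seconds, out of a
900-second observation by default),

$$\mathrm{SOP} = \frac{T_C - T_H}{T_C + T_H} \in [-1, 1].$$

Time in the neutral zone does not enter: SOP conditions on the time the
fish spent assessing either stimulus. It is invariant to rescaling both
times, antisymmetric under swapping them, and undefined when both are zero
(a fish that never entered either zone expresses no preference; such
trials are excluded from summaries with a warning rather than scored 0,
since 0 would assert indifference the data cannot support). SOP also reads
as the proportional reduction in gene flow relative to random mating,
which is why group means, not just their signs, are biologically
interpretable.

**Isolation index.** For free-interaction stream trials, each of five
behavior classes (spawning; successful and unsuccessful male solicitation;
male–male chases; male chases of females) is tallied per replicate toward
conspecific and heterospecific targets. With $C$ and $H$ the mean counts
across replicates,

$$I = \frac{C - H}{C + H},$$

computed per behavior, and as *total isolation* by first summing the five
classes within each replicate and species. Two aggregation orders exist
for the population level: index the averaged summed counts, or average the
per-replicate indices. These differ (the index is a nonlinear ratio);
`population_total_isolation()` implements the first — averaging counts
before indexing — because that is the convention for the Stalker-style
statistic, and the per-replicate indices remain available from
`total_isolation_per_replicate()` for the GLS. Both-means-zero yields a
missing index, never 0 and never an error: the ratio is undefined, and a
never-observed behavior should surface as a gap in the table (rendered as
a dash), not as evidence of no bias.

## The linear model for SOP

The design crosses sex with population, and population is nested within
geographic context: a population is either sympatric or allopatric, so
there is no population main effect *across* contexts. `fit_sop_model()`
encodes this directly: sum-to-zero contrasts for context and sex,
context-specific sum-to-zero contrasts among the populations of each
context (2 df for four populations in two contexts), and a combined
`population:sex` interaction spanning sex-by-context and
sex-by-population-within-context (3 df). Because `population:sex` contains
the `context:sex` contrasts, the two terms are mutually exclusive in one
model, and the fitter refuses aliased designs by name rather than silently
dropping columns.

Sums of squares are Type III (marginal) by default: the cell counts are
unbalanced whenever one collection ran short (the synthetic dataset
reproduces a 16-fish male cell among 18s), and term-wise tests in
unbalanced designs should not depend on term order. Sequential Type I is
available behind a flag for variance-decomposition reading. Each term's F
statistic comes from the RSS difference between the full design and the
design with that term's columns deleted, on the full-model residual df.

**Backward selection** (`backward_select()`) starts from the full model
and repeatedly deletes the single *eligible* term with the largest
p value above `alpha` (default 0.05), refitting after each deletion. A
term is eligible only if no retained term contains it under the nesting
closure (population implies context), so a significant interaction
protects all of its constituent main effects — the marginality principle.
One term per step, largest p first, makes the procedure deterministic
where "sequentially remove nonsignificant variables" alone would not be.

**Least-squares means** (`lsmeans_contrasts()`) are fitted cell means
averaged with equal weights over the levels of the other factors; for the
nested design a context LS-mean averages over that context's population
× sex cells, and a population LS-mean fixes context at the population's
own. Pairwise contrasts use the model residual df, and the Bonferroni
family is exactly the set of contrasts emitted by one call — the smallest
family that is still well-defined without knowing which comparisons a
reader plans. Contrasts touching a design cell with no observations are
flagged inestimable rather than reported.

## The heteroskedastic GLS for total isolation

Per-replicate total isolation is modeled as a linear function of fixed
effects (default: context) with a separate residual variance per variance
group (default: context) — sympatric replicates cluster near the ceiling
of the index while allopatric replicates spread widely, so a common
variance would misweight the contrast. The fit alternates weighted least
squares for the coefficients with maximum-likelihood variance updates
(mean squared residual per group) until the relative change in variances
is below 1e-8; this coordinate ascent converges to the ML heteroskedastic
fit, and when the realized group variances are equal it reproduces OLS
exactly. Standard errors are the ML ones,
$\sqrt{\mathrm{diag}[(X'\hat\Sigma^{-1}X)^{-1}]}$, with t tests on
$n - p$ df; nlme's `gls` reports the same covariance inflated by
$n/(n-p)$, a conversion the test suite applies when cross-checking.

Context coding follows the resident-species rule: in a two-species assay
the congener is at home at every trial site, so `resident_species` recodes
all of its rows as sympatric while the focal species keeps its
population's context. A variance group collapsing to (numerically) zero
residual variance aborts with a diagnostic — weights of $10^{12}$ are an
answer to a question nobody asked.

The trial-replicate random effect that such designs sometimes carry is
available as an exchangeable within-replicate residual correlation
(`replicate_effect = TRUE`, moment-estimated and clipped to $\pm 0.9$);
the default model omits it, matching the common outcome that it does not
survive model selection with three replicates per population.

## Rank tests, t tests, effect size

`mann_whitney()` and `wilcoxon_signed_rank()` report the classical U and
W statistics, a normal-approximation Z with the tie correction always
applied and a 0.5 continuity correction (the convention behind most
published Z values), and an exact two-sided p by complete enumeration —
all $\binom{N}{n_a}$ labelings for Mann–Whitney at combined $N \le 20$
without ties, all $2^n$ sign patterns for the signed-rank test at
$n \le 12$ nonzero untied differences. Where the exact p exists it is the
reported one. Zero differences are dropped (Wilcoxon convention);
all-identical inputs return a flagged degenerate result, never NaN.
`one_sample_t()` delegates to the standard t machinery; `cohens_d()` uses
the pooled-SD definition. The choice between t and Wilcoxon for group SOP
summaries is an explicit argument (`test =`) defaulting to t, since
published analyses switch between them without a stated rule.

## What the synthetic generator emulates

`simulate_dichotomous()` allocates each trial's time in two beta
distributed stages: an activity fraction $a$ with mean `activity_mean`
(default 0.75) and precision `activity_precision` (default 10) sets total
association time $A = 900a$; a conspecific share $c$ with mean
$(1+\beta)/2$ and precision $\kappa$ splits it, giving
$T_C = Ac,\; T_H = A(1-c)$. Since $\mathrm{SOP} = 2c - 1$ regardless of
$A$, $E[\mathrm{SOP}] = \beta$ exactly — the estimand is the parameter,
with no attenuation — and $T_C + T_H \le 900$ holds by construction. The
default $\kappa = 5$ gives an SOP standard deviation near 0.41 at
$\beta = 0$, in the middle of the range implied by reported group
standard errors (0.03–0.15 at $n \approx 18$) in this literature; at
$n = 18$ a cell mean therefore carries a standard error near 0.1, which
is why the recovery tests bound deviations by three *estimated* standard
errors rather than a fixed constant.

`simulate_stream()` draws each replicate × species × behavior pair of
counts with means $\lambda(1\pm\iota)/2$, Poisson at `dispersion = 0` and
gamma-mixed (negative binomial, variance $\mu + \phi\mu^2$) otherwise.
The default `dispersion = 0.3` makes standard deviations comparable to or
larger than means at realistic $\lambda$, as free-interaction count data
show. Rates may be given per species: `make_paper_like_dataset()` uses
this so the resident congener keeps a strong conspecific bias
($\iota = 0.9$ for solicitation) in every trial, while the focal species'
solicitation bias drops from 0.90 in sympatry to 0.45 in allopatry —
the generator's encoding of the observation that allopatric males court
heterospecific females. Spawning uses $\lambda = 3$ with $\iota = 0.95$,
so heterospecific spawning is a rare event. Seeds drive per-group
substreams derived by hashing the group labels, so adding a group never
perturbs existing groups' draws, and identical seeds are bit-identical.

What the generator does *not* emulate: within-trial temporal dynamics or
side bias (times are allocated, not simulated as movement), correlation
between an individual's dichotomous and stream behavior, repeated use of
individuals across stream replicates, and any deviation from the
beta/negative-binomial families. Passing recovery and calibration tests
therefore show that the *estimators and tests* behave correctly under a
plausible data-generating process — not that real darter data follow
these distributions.

## Numerical and reporting choices

- All computation is double precision; rounding (half-even, via `round()`)
  happens only at the render layer, at 2 decimals by default, matching how
  such tables are printed.
- Validation is total: every malformed input raises a typed condition
  (`reinfiso_schema_error`, `reinfiso_validation_error`,
  `reinfiso_consistency_error`, `reinfiso_domain_error`,
  `reinfiso_config_error`) citing the offending rows; no partially loaded
  dataset ever escapes the readers.
- Blank optional CSV fields are missing, never zero; neutral-zone time is
  not stored since it is derivable.
- The GLS convergence tolerance (1e-8 relative change in variances) and
  the rank-deficiency checks are deliberately strict; degenerate cases
  abort or flag rather than approximate.
- Test and calibration problem sizes: the ANOVA oracle runs on ≤ 30-row
  fixtures; null calibration uses 1,000 simulated studies at 18 trials per
  group; power comparisons use 400 simulations at 36 per group. These
  sizes give Monte-Carlo error comfortably inside the asserted bands
  (rejection-rate SE ≈ 0.007 at 1,000 reps).

## Known limitations

- The SOP model assumes independent trials; it has no random effect for
  stimulus identity or test day.
- The GLS t tests use $n - p$ df without a Satterthwaite-style
  adjustment; with very small variance groups the test can run slightly
  liberal (the calibration test bounds this at the study's scale).
- Exact rank-test enumeration is limited to the stated small-n ranges;
  beyond them only the corrected normal approximation is reported.
- The isolation index treats counts as exchangeable across behaviors when
  totaled; a behavior with a large rate dominates the total by design,
  which is why the behavior-exclusion sensitivity analysis
  (`exclude_behaviors_sensitivity()`) is part of the standard pipeline.
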