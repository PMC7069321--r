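# reinfiso

Quantifying behavioral reproductive isolation from mate-choice trials, and
testing for the classic signature of reinforcement: stronger conspecific
preference in populations sympatric with a congener than in allopatric
populations.

The package serves behavioral ecologists and speciation researchers working
with two standard experimental designs:

- **Dichotomous choice trials** — a focal individual sees a conspecific and
  a heterospecific stimulus (no physical contact) for a 15-minute
  observation; time in each association zone is recorded. The
  per-individual **strength of preference** is

  ```
  SOP = (T_C - T_H) / (T_C + T_H)
  ```

  where `T_C` and `T_H` are the conspecific and heterospecific association
  times. SOP ranges from +1 (complete conspecific preference) to -1, and
  can be read as the proportional reduction in gene flow relative to
  random mating.

- **Artificial stream (free-interaction) trials** — several individuals of
  both sexes and species interact freely; five behavior classes are
  tallied per replicate (spawning, successful and unsuccessful male
  solicitation, male–male chases, male chases of females), each directed
  at conspecifics or heterospecifics. The Stalker-style **isolation
  index** for a behavior is

  ```
  I = (C - H) / (C + H)
  ```

  with `C` and `H` the mean conspecific- and heterospecific-directed
  counts across replicates. **Total isolation** sums counts over all
  behavior classes per replicate before indexing.

Around these indices the package implements the full inference chain such
studies use: a nested linear model for SOP (population within geographic
context) with Type III tests and backward term selection, least-squares
means with Bonferroni-adjusted contrasts, Mann–Whitney and Wilcoxon tests
with exact enumeration at small n, Cohen's d, and a heteroskedastic
generalized least-squares model for total isolation (separate residual
variance per context, resident species coded as sympatric everywhere). A
synthetic-trial generator with known preference (`beta`) and bias (`iota`)
parameters makes every stage testable: parameter recovery, type-I-error
calibration, and power analysis.

## Worked example

```r
library(reinfiso)

ds  <- make_paper_like_dataset(seed = 1)   # 142 trials, 12 stream replicates
rec <- sop_records(ds$trials)
group_sop_summary(rec, c("context", "sex"))
#>      context    sex  n  mean     se    test_name statistic df  p_value
#> 1 allopatric female 36 0.275 0.0572 t_one_sample      4.80 35 2.95e-05
#> 2 allopatric   male 36 0.283 0.0609 t_one_sample      4.65 35 4.60e-05
#> 3  sympatric female 36 0.544 0.0648 t_one_sample      8.40 35 6.51e-10
#> 4  sympatric   male 34 0.317 0.0496 t_one_sample      6.39 33 3.04e-07
```

Every group prefers conspecifics (mean SOP > 0), and sympatric females
most strongly — the configured generator biases are recovered. The nested
model and its context contrast:

```r
sel <- backward_select(rec)
sel$final_fit
#> Linear model for SOP (Type III tests), n = 142
#>            term df    sum_sq f_value p_value
#>         context  1 0.8014974   6.956 0.00934
#>             sex  1 0.4357182   3.781 0.05390
#>      population  2 0.5968196   2.590 0.07880
#>  population:sex  3 1.2549161   3.630 0.01470
#> Residual df: 134

lsmeans_contrasts(sel$final_fit, "context")$contrasts
#>                 contrast estimate    se t_statistic  df   p_raw p_adjusted
#> 1 allopatric - sympatric    -0.15 0.057       -2.64 134 0.00934    0.00934
```

Context is significant: sympatric populations prefer conspecifics more
strongly, the reinforcement signature. On the stream side, total isolation
is higher in sympatry:

```r
rt <- total_isolation_per_replicate(ds$stream_counts)
fit_total_isolation_gls(rt, resident_species = "E. barrenense")
#> Heteroskedastic GLS for total isolation (n = 24, logLik = 29.847)
#>              term estimate     se t_statistic df  p_value
#>       (Intercept)   0.7240 0.0462      15.688 22 1.99e-13
#>  contextsympatric   0.1196 0.0482       2.480 22 2.13e-02
#> Residual variance by context: allopatric=0.01278, sympatric=0.003529
```

The intercept is the mean allopatric total isolation (0.72); sympatric
replicates run about 0.12 higher (p = 0.02), with visibly larger residual
variance on the allopatric side — the reason for the heteroskedastic model.
`exclude_behaviors_sensitivity()` then recomputes totals without the male
solicitation classes to ask whether those behaviors alone carry the
difference, and `run_pipeline(pipeline_config(simulate = TRUE, seed = 1))`
executes all of the above plus the per-behavior isolation table in one
deterministic call.

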