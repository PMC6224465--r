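# hyperdisc

Tools for within-subject intertemporal-choice experiments on context and
framing effects in delay discounting — in particular the **magnitude
effect** (people discount less steeply when all amounts are scaled up) and
the **hidden-zero effect** (people are more patient when the implicit zero
outcomes are stated, e.g. "$20 today and $0 in 14 days"). The package is
aimed at decision-modelling researchers who want a fully scripted,
reproducible pipeline from raw binary choices to study-level statistics,
plus a synthetic-agent generator that makes every stage testable without
human data.

## The model

Each trial is a binary choice between a smaller-sooner reward `r1`
(available immediately) and a larger-later reward `r2` after `t` days
(14 or 28). Subjective value follows a hyperbolic discount function

    V = r / (1 + k t)

with discount rate `k` per day (higher `k` = more impulsive). Choices are
generated (and fitted) through a softmax (logistic) rule on the subjective
value difference,

    P(LL) = 1 / (1 + exp(-alpha * (V_LL - V_SS))),

with inverse temperature `alpha` per dollar. For one cell (subject x
condition x stimulation level), `(k, alpha)` is estimated by maximum
likelihood over `(ln k, ln alpha)` inside a bounded box, using an
L-BFGS-B local search restarted from 50 uniform random points.

Every choice has an indifference rate `k_eq = (r2 - r1) / (r1 t)`, the
`k` at which both options are worth the same; it drives the model-free
diagnostics (correct-choice rate, pSS by median split on `k_eq`).

Study-level inference uses 2 (hemisphere, between) x 2 (condition) x 2
(stimulation) type-III mixed ANOVAs on `ln k` with generalized eta squared
(η²_g), paired t tests, and a two-sided Fisher's exact test comparing how
often stimulation reduced each effect across subjects (with the sample
odds ratio `ad/bc`).

## Worked example

Simulate a study with the default generative structure (27 subjects,
15 left / 12 right; a large magnitude effect on `ln k`, a smaller
hidden-zero effect, and a stimulation x magnitude interaction that
selectively shrinks the magnitude effect), fit every cell, and run the
statistics:

```r
library(hyperdisc)

cfg   <- study_config(seed = 42)
study <- simulate_study(cfg)
study
#> Simulated discounting study
#>   27 subjects, 4860 trials (243 cells x 20 choices)
#>   seed 42

trials <- subset(study$trials, stim_level %in% c("sham", "tms"))
fits   <- fit_study(trials, seed = 42)
head(fits[, c("subject", "stim_level", "condition", "log_k", "alpha", "nll")], 3)
#>   subject stim_level condition      log_k  alpha   nll
#> 1 s01     sham       control        -4.53 15.0    1.34
#> 2 s01     tms        control        -4.55  1.36   6.34
#> 3 s01     sham       high_magnitude -6.25  0.0855 4.36

condition_anova(fits, "magnitude", reference = "sham")
#>   effect                     df1   df2 statistic      ges     p_value
#> 1 hemisphere                   1    25    0.0527 0.000793 0.820
#> 2 magnitude                    1    25    3.10   0.0225   0.0904
#> 3 hemisphere:magnitude         1    25    2.02   0.0148   0.167
#> 4 tms                          1    25   47.1    0.290    0.000000343
#> 5 hemisphere:tms               1    25    2.43   0.0206   0.131
#> 6 magnitude:tms                1    25   42.4    0.273    0.000000799
#> 7 hemisphere:magnitude:tms     1    25    4.21   0.0359   0.0508

compare_effect_reductions(fits, reference = "sham")
#> Effect reductions under tms (reference: sham)
#>   effect      n_reduced n_total
#> 1 magnitude          25      27
#> 2 hidden_zero        10      27
#> two-sided Fisher's exact test (minimum-likelihood rule)
#> sample odds ratio = 21.25, p = 3.365e-05
```

Reading the output: each fitted cell reports the log discount rate
`log_k` (here s01 is near `ln k = -4.5`, i.e. roughly indifferent between
$20 now and $24 in two weeks) and the choice-noise parameter `alpha`. The
ANOVA shows the simulated magnitude x stimulation interaction clearly
(`F(1, 25) = 42.4, p < 1e-6, η²_g = 0.27`), while the fitted magnitude
*main* effect is diluted by the few agents whose true rate lies outside
the high-magnitude set's measurable `k_eq` range (their one-sided response
patterns push the ML estimate to a bound — see the vignette). The
reduction comparison shows stimulation shrinking the magnitude effect for
25 of 27 agents but the (generatively untouched) hidden-zero effect for
only 10 of 27.

`run_pipeline(out_dir)` chains all of the above (simulation or an external
trial table, fits, per-cell diagnostics, ANOVA tables, reduction
comparison) and writes each stage as a TSV plus a JSON run manifest;
identical config and seed give byte-identical outputs.

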