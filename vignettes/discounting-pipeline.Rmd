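---
title: "Modelling context effects in delay discounting: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling context effects in delay discounting: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hyperdisc)
```

This vignette explains the models and procedures implemented in
`hyperdisc`, the assumptions behind them, and the design choices made
where more than one reasonable implementation existed. It states no
empirical result that the test suite does not itself compute.

## The experimental design being modelled

The package targets a within-subject intertemporal-choice design with
three framing/context conditions — `control`, `high_magnitude`, and
`explicit_zero` — crossed with three stimulation levels: a
`pre_experiment` baseline, `sham`, and active `tms`. Subjects are split
into two between-subject groups by stimulated hemisphere (left/right).
Each cell presents 20 binary choices between a smaller-sooner amount
`r1`, available immediately, and a larger-later amount `r2` after 14 or
28 days.

### Choice-set construction

Choice difficulty is controlled through a fixed multiset of percent
differences `r2/r1 - 1`: 1%, 5%, 10%, 20%, 30%, 40% with three choices
each plus 50% with two, for the low-magnitude conditions; the
high-magnitude condition divides every tier by ten (0.1%–5%) while
keeping the counts. Amounts are sampled from N(20, 5) dollars
(low-magnitude) or N(2000, 500) (high-magnitude). Dividing the tiers by
ten is what keeps the high-magnitude choices informative: the magnitude
effect is large enough that fixed proportional differences would make
those choices one-sided.

Design choices where the construction rules leave freedom:

* **Truncation.** Normal draws are redrawn while non-positive. At these
  parameters negative draws are vanishingly rare (4σ events), but the
  sampler must be total.
* **Rounding.** `r1` is rounded to cents, then `r2 = r1 (1 + d)` is
  rounded to cents. The realized ratio therefore deviates from the tier
  fraction by at most half a cent over `r1`, and validation checks
  `|r2 - r1 (1 + d)| <= 0.005`.
* **Delay balancing.** The printed constraints — ten choices per delay,
  and both delays present in every percent tier — underdetermine the
  assignment. We satisfy them by construction: the two-choice 50% tier
  gets one choice at each delay; of the six three-choice tiers, a random
  three get two 14-day choices and the other three get two 28-day
  choices, giving `1 + 2*3 + 3 = 10` choices at each delay exactly.
  (Note a 4/2 split of the tiers cannot satisfy the 10/10 constraint.)
* **Independence.** `r1` is sampled independently for every choice; the
  10/10 delay split is enforced exactly.
* **Amount display.** Amounts are decimal dollar values rendered with two
  decimals; the integer-amount glitch that affected a few original
  subjects is deliberately not emulated.

## The discounting model

Subjective value is hyperbolic, `V = r / (1 + k t)` with `k` per day, and
choice follows a binary softmax on the value difference,
`P(LL) = logistic(alpha (V_LL - V_SS))` with `V_SS = r1` (immediate
rewards are undiscounted). The "softmax" is implemented as the logistic
on the raw dollar-scale difference; because every cell is fitted
separately, the dollar-scale dependence of `alpha` is absorbed per cell.

Every choice has a closed-form indifference rate
`k_eq = (r2 - r1)/(r1 t)`. Numerically, the value difference is computed
as `r1 t (k_eq - k) / (1 + k t)` — algebraically identical to
`r2/(1 + k t) - r1`, but exactly zero in floating point at `k = k_eq`, so
the indifference identity `P = 1/2` holds to machine precision for any
`alpha`.

### Estimation

Per-cell maximum likelihood over `(ln k, ln alpha)`:

* **Bounds.** `k` in `[1e-6, 10]` per day, `alpha` in `[1e-4, 100]` per
  dollar. On these choice sets that spans indifference horizons from
  seconds to years; hits on the bounds are flagged in the fit metadata.
* **Multi-start.** 50 restarts of a bounded L-BFGS-B search (analytic
  gradient) from points uniform in the log-box. Log-space removes the
  scale pathologies of `k`, and the restarts guard against local minima;
  the test suite compares the multistart optimum against a dense
  200 x 200 log-spaced grid search with local polish.
* **Clipping.** Per-trial probabilities are clipped at `1e-12` before the
  log so the objective is finite over the whole box.
* **Missing responses** (the task allows time-outs) are dropped before
  fitting and tallied per cell.
* `alpha` is fitted per cell rather than shared within subject, matching
  a design in which each condition's discount rate is estimated
  separately.

The estimator is *censored* outside the choice set's `k_eq` range: an
agent whose true `k` exceeds every `k_eq` answers smaller-sooner
throughout, and any sufficiently large `k` fits those data equally well,
so the estimate runs to a bound. Parameter-recovery checks therefore
sample true rates inside the identifiable range (uniform `ln k` over
about 0.002–0.03 per day for the low-magnitude sets, which span `k_eq`
from 3.6e-4 to 3.6e-2); recovery claims outside that range would be
claims about the bounds, not the estimator.

### Choice diagnostics

* `classify_correct`: a response is correct when it matches the
  preference implied by the cell's fitted `k` (smaller-sooner iff
  `k > k_eq`); exact ties are correct either way, since the model is
  genuinely indifferent and penalizing either response would be
  arbitrary.
* `pss`: fraction of smaller-sooner responses among responded trials.
* `median_split_pss`: the cell's trials are ordered by `k_eq` and split
  into equal halves (for 20 choices, the 10 smallest vs 10 largest, ties
  broken by stable order); a subject tracking subjective value should
  show higher pSS in the low-`k_eq` half.

## The synthetic-agent generator

`study_config()` fixes the generative model; `simulate_study()` draws a
full study (fresh choice set per cell, Bernoulli responses at the cell's
true parameters), with all randomness derived from one root seed via
label-hashed child seeds, so results are order-independent and exactly
reproducible.

Per-cell truth: `ln k = baseline + shifts + session noise`, with the
baseline per subject from `N(mu_logk_control, sigma_logk_between^2)` and
independent `N(0, sigma_logk_session^2)` noise per cell. The session
noise is per cell (not per session) so that the within-subject error
stratum of the ANOVA is non-degenerate at truth level. The
`pre_experiment` and `sham` levels are generated identically — two
no-stimulation baselines differing only by session noise.

Default parameter values (invented, overridable, stated in the config):

| parameter | default | rationale |
|---|---|---|
| `mu_logk_control` | `ln 0.01` | average agent near indifference on the 20%/2-week choice |
| `sigma_logk_between` | 0.8 | wide, realistic individual differences |
| `sigma_logk_session` | 0.3 | day-to-day wobble; not reported anywhere, free knob |
| `magnitude_shift` | −2.0 | large baseline magnitude effect |
| `hidden_zero_shift` | −0.4 | smaller framing effect |
| `tms_main` | 0 | no overall stimulation effect |
| `tms_magnitude_interaction` | +1.5 | stimulation selectively shrinks the magnitude effect |
| `hemisphere_shift` | 0 | no hemisphere effect (knob for power studies) |
| `alpha` (control / explicit zero) | 1.0 per dollar | high but imperfect consistency on ~$20 stakes |
| `alpha` (high magnitude) | 0.1 per dollar | see below |

The high-magnitude `alpha` is ten times smaller than the low-magnitude
value because the dollar-scale value differences are about ten times
larger there: amounts are 100x larger but percent differences are 10x
smaller. Scaling by 1/10 equates the typical softmax argument across
conditions, i.e. equal choice consistency — a much smaller value would
make high-magnitude agents respond near chance and the condition
uninformative.

What the generator does *not* emulate: response times, fatigue or order
effects across sessions, subject dropout, the integer-amount coding
glitch, and any dependence of `alpha` on stimulation. Passing tests
therefore show that the pipeline is correct and well-calibrated under an
additive-on-`ln k` world with softmax choice; they cannot show that real
subjects satisfy those assumptions.

## Study-level statistics

### Mixed ANOVA with generalized eta squared

`mixed_anova()` analyses the 2 (between) x 2 x 2 (within) design through
orthonormal within-subject contrast scores: each subject's four cell
values are projected onto the mean, the two within main-effect contrasts,
and the interaction contrast (coefficients ±1/2, so total SS decomposes
exactly). Each score vector forms its own error stratum and is tested
against the between factor with sum-to-zero coding and type-III sums of
squares — computed in closed form from cell means, the intercept test
being on the *unweighted* mean of group means, which is what type III
means for the unbalanced 15/12 hemisphere split. For balanced groups this
reproduces `aov()` error-strata output exactly (a test asserts this), and
an independent type-III cross-check against `car::Anova` covers the
unbalanced case.

Generalized eta squared is
`SS_effect / (SS_effect + sum of all subject-related error SS)`, the
denominator pooling the between-subject error and all three
within-stratum errors, making effect sizes comparable across between- and
within-subject effects (and never exceeding the corresponding partial eta
squared).

Sphericity: every within factor here has two levels, so each within
effect has a single contrast and the Greenhouse–Geisser epsilon —
`tr(M)^2 / (d tr(M^2))` for the `d x d` contrast covariance — is
identically 1. The correction is therefore the identity and uncorrected
df are reported; tables with more than two within levels are rejected
rather than silently uncorrected.

Degenerate inputs: a constant response yields `F = 0`, `p = 1`,
`η²_g = 0` for every effect; unbalanced or duplicated within-cells raise
an error naming the offending subject; a single-group between factor
drops the between terms.

### Paired t, reduction counts, Fisher's exact test

`paired_t()` is the classical two-sided paired t with `df = n - 1`
(zero-variance differences are handled as an explicit degenerate case).
The t tests here are reported with `df = n - 1`; other df conventions
for pooled post-hoc contrasts are not emulated.

A subject's *effect size* at a stimulation level is
`ln k(control) - ln k(effect condition)`; the subject counts as *reduced*
when that difference is strictly smaller under `tms` than under the
chosen no-stimulation reference (ties, measure-zero under the generator,
count as not reduced). The two reduction proportions (magnitude vs
hidden-zero) are compared by a two-sided Fisher's exact test using the
minimum-likelihood rule — summing hypergeometric point probabilities no
larger than the observed table's (relative tolerance `1 + 1e-7`, as in
mainstream implementations) — with the **sample** odds ratio `ad/bc`
reported, not the conditional-MLE value, because the cross-product ratio
is the quantity conventionally quoted alongside this comparison. The
p-value is verified in tests against brute-force enumeration over all
tables with the observed margins and against `stats::fisher.test`.

## Calibration and power checks

Two properties tie the generator and the ANOVA together, both computed on
replicate simulated studies at n = 27:

* **Type-I calibration**: with every generative effect set to zero, the
  magnitude x stimulation interaction should reject at the 5% level in
  about 5% of studies.
* **Power**: at the default effect sizes, the interaction should be
  detected in well over 80% of studies.

These are computed over 200 replicate studies each, with the response
taken from the study's ground-truth per-cell `ln k` table. Using the
truth table isolates the property being tested — the calibration of the
generative model plus the test statistic — from estimation noise, which
is characterized separately by the parameter-recovery check (200 agents,
60 trials each); a full end-to-end replicate (simulate, fit every cell by
multistart ML, test) is exercised separately and shows the same
interaction. Problem sizes throughout (200 replicates, 200 agents,
1000-seed design sweeps, 50-instance grid comparisons) were chosen as the
smallest runs that make the Monte-Carlo error clearly smaller than the
tolerance being asserted.

## Known limitations

* Only the hyperbolic discount function is implemented — no exponential
  or quasi-hyperbolic alternatives, and no hierarchical/Bayesian pooling
  across subjects.
* Per-cell ML estimates are censored at the parameter bounds when an
  agent's rate falls outside the choice set's `k_eq` range; group *means*
  of fitted `ln k` are sensitive to these boundary fits (medians are
  not). This is a property of the design plus estimator, not a bug, and
  it is visible in the simulated end-to-end analyses.
* `alpha` is weakly identified when choices are nearly deterministic
  (only its lower range changes the likelihood appreciably), which is why
  no inferential claims are made about the noise parameter.
* The pipeline's ANOVA machinery is deliberately restricted to the
  2 x 2 (x 2) mixed design it was built for.
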