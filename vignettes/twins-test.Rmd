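---
title: "Detecting parity-dependent fertility control with twin births"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting parity-dependent fertility control with twin births}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinstest)
```

## The question and the design

Whether pre-industrial couples limited their fertility once they had "enough"
children — parity-dependent control — is contested. Classical natural-fertility
diagnostics (age patterns of marital fertility, stopping ages) presuppose an
uncontrolled reference population and detect only particular forms of control.
The twin-birth design sidesteps both problems: a twin delivery is an
essentially random +1 shock to family size at a known parity. If couples do
not react, families experiencing a twin end up with exactly one extra birth on
average, whatever the parity at which the twin arrived. If couples hold a
target number of surviving children, they compensate: the extra twin crowds
out later births, and more so the lower the parity at which it lands.

`twinstest` packages that design end to end: a microsimulator of marital
birth histories under configurable regimes, the least-squares twin-effect
estimators, the closed-form expected effects under the two polar regimes,
mixture bounds on the share of controlling couples, and register-quality
diagnostics.

## The estimators

Each delivery is one observation. For total births `NB` (children ever born
to the family) the parametric regression is

    NB ~ alpha_b * TWIN + parity indicators + mother-age indicators

with single-year mother-age indicators pooled below 16 and above 49, and the
analogous regression for `NS`, children surviving to age 14. The fully
interacted variant replaces the additive blocks with one indicator per
occupied parity-by-age cell; it is computed by within-cell demeaning
(Frisch–Waugh–Lovell), which is the same least-squares problem solved
without materialising hundreds of dummy columns. Cells containing no twin
delivery stay in the fixed-effect set; they simply contribute nothing to the
twin coefficient. Two further regressions probe the mechanics: a
twin-by-parity interaction (`estimate_parity_interaction()`, slope zero under
natural fertility, positive under targeting) and the interval to the next
delivery (`estimate_post_twin_interval()`, zero under natural fertility,
positive if couples space after a twin).

Conventional OLS standard errors are the default. Families contribute one row
per delivery and the outcome is family-level, so residuals are correlated
within family; `cluster_se = TRUE` switches to family-clustered standard
errors for users who prefer the conservative choice.

## The two poles and the mixture bound

With survival-to-14 probabilities `theta_s` (singletons) and `theta_t` (each
twin), and `phi` the fraction of births that are a family's last planned
birth (`1 / mean births`, since every completed family has exactly one last
birth):

| | no control | complete control |
|---|---|---|
| extra births | 1 | `2(1 - theta_t/theta_s)(1 - phi) + phi` |
| extra survivors | `2 theta_t - theta_s` | `phi (2 theta_t - theta_s)` |

A population mixing a fraction `p` of controllers yields the linear mixture
of the two poles, so an estimated coefficient inverts to a point share and,
sliding the estimate by a normal quantile of its standard error, to a
one-sided confidence bound (`controller_share_bound()`), truncated into
`[0, 1]` after computation. `controller_share_probability()` gives the
companion statement "with probability q, fewer than x% of couples held
targets", treating the estimate as normal around the mixture coefficient
with a flat prior on the share (no truncation; a threshold of 1 returns 1
exactly, since a share cannot exceed 1). We use standard-normal rather than
Student-t quantiles throughout: the design's applications have five- to
six-figure observation counts. These normal-approximation inversions are
validated in the test suite against a Monte-Carlo test inversion that
simulates the sampling distribution of the estimate under each candidate
mixture.

## What the simulator emulates

`simulate_cohort()` advances in monthly steps. Per couple: a marriage age
(normal, default mean 25, sd 4), a per-woman sterility age (default 41, sd
4), peak monthly fecundability (default 0.18) constant to age 30 and then
declining linearly to zero at the sterility age, nine months' gestation, a
post-partum non-susceptible period (mean 11 months — gestational amenorrhoea
plus breastfeeding, the main regulator of historical birth intervals), and a
constant annual death hazard per parent (default 0.008). Reproduction ends at
sterility, at `max_wife_age` (50), or at the first parent death. These
defaults were chosen once to give realistic pre-industrial birth intervals of
roughly 26 months and completed family sizes in the published 3.4–6.0 range;
the six `cohort_preset()` populations then fix survival rates and twinning
rates at their published values and calibrate only marriage age and
fecundability so that realized mean births match the published averages
(verified to ±0.3 at large cohort sizes in the test suite). No published
fecundability or interval distributions exist for these samples, so the
presets reproduce means, not interval shapes.

Twinning is per conception: a base rate plus small additive gradients in
mother's age (default 0.0004 per year above 20) and parity (0.0006 per prior
delivery), values in the range reported for historical registers.
Monozygotic twinning is modelled as a constant 0.004 of conceptions (about
0.8 MZ children per 100 births, the near-universal rate); MZ pairs share a
sex, dizygotic pairs draw sexes independently. This constant-MZ structure is
what makes the same-sex diagnostic meaningful: with it, the implied
detection fraction inverts to 1 on a fully detected simulated register at
any configured twinning rate. Twin survival draws are independent within the
pair, consistent with using a single per-child twin survival probability; an
optional per-family lognormal twin-propensity multiplier
(`family_twin_log_sd`) reproduces the mild familial repetition excess seen
in real registers, and is off by default because random allocation accounts
for most repetition.

Controllers hold a target number of children *surviving to 14*, drawn from
`1 + Poisson(target_mean - 1)`. The default stopping rule is
perfect-foresight: a couple ceases exposure once the children already born
will eventually number the target — the counterpart of the closed-form
algebra, which assumes the target is attained exactly. A reactive variant
(stop while currently-alive children meet the target, resume after a child
death) is available as a configuration switch; the two rules coincide
exactly when no child dies, which the test suite checks.

What the simulator does *not* emulate: remarriage and marriage markets,
breastfeeding heterogeneity, economic shocks to spacing, maternal death in
childbirth as distinct from background adult mortality, and twin-specific
gestation length. Passing recovery tests on these cohorts therefore shows
that the estimators measure what the design intends under the design's own
assumptions — not that any particular historical population was uncontrolled.

## Numerical and design choices

* **Parity** counts prior *deliveries* (a twin pair advances parity by one),
  0-based, matching the comparison of a twin delivery with a singleton
  delivery at the same event order.
* **Unknown death dates** are an explicit `NA`, never a sentinel age, and
  the default sample filter keeps families whose relevant parent has no
  death record (mothers must not be *known* to have died before 40, fathers
  before 45). Simulated deaths after age 80 are recorded as `NA` — by then
  reproduction is long over and real registers rarely link such burials.
* **Degenerate cells**: single-observation parity-age cells contribute zero
  residual under least squares and need no special handling. If no cell
  mixes twin and singleton deliveries the twin effect is unidentified and
  estimators raise a classed error rather than returning a number.
* **Identification guards**: tables with no twin rows, twins at a single
  parity (for the interaction), or no twin with a recorded next interval all
  raise `twinstest_unidentified`.
* **Determinism**: every stochastic entry point takes a seed; the pipeline
  writes byte-identical outputs for identical configurations and seeds.

## Validation choices and known limitations

The natural-fertility recovery checks simulate 50,000 families — large
enough that the twin coefficient's standard error (~0.035) separates the
two poles (about 1 vs 0.5) by many standard errors, yet cheap enough that
the whole suite runs in about a minute of simulation time.

The complete-control recovery check deserves honesty about its conditions.
The closed-form pole assumes every family completes its planned births.
Under realistic marriage ages, sterility spread and adult mortality, 10–20%
of simulated controller couples never attain their target — their spans are
truncated first — and those couples respond to a twin like natural-fertility
couples, pulling the estimated coefficient well above the pole. The
validation cohort therefore realizes the algebra's assumptions directly:
marriage at 20 (sd 1), sterility at 45 (sd 1), no adult mortality, targets
capped at three survivors. Attainment is then ~99.5% and is verified in the
test independently of the coefficient. One discreteness gap remains even
then: a twin that crosses the target from a deficit of one leaves the family
with one survivor *more* than planned, so the exact process sits slightly
above `phi (2 theta_t - theta_s)` for survivors (by roughly
`phi * theta_t^2 / theta_s` worth of overshoot, ~0.03–0.06 here). The
recovery tests run at the 2-standard-error tolerance appropriate to the
cohort size; the survivors check passes there, but users probing the
survivors pole at much larger simulated cohorts will resolve the overshoot
as a real, documented difference between the discrete stopping process and
the linearized algebra.

The same-sex misclassification diagnostics distinguish two register failure
modes with opposite signatures (`corrupt_twin_labels()`): *false* twin
labels (non-twin siblings baptised the same day) dilute the same-sex ratio
and bias the twin effect towards "finding control", but leave the implied
detection fraction nearly unchanged, because they inflate the observed
twinning rate in the same proportion; *missed* true twins lower the implied
detection fraction proportionally. The diagnostic's inversion is therefore a
test of how much of the true twinning signal is present, not of label
purity.

## A worked run

```{r, eval = FALSE}
res <- run_pipeline(run_config(preset = "england_pre1880",
                               n_families = 50000, seed = 1))
res$estimates$births
res$theory$bounds$births
autoplot(res$profile)
```

The report bundle mirrors how the design is read in practice: the estimated
twin effects sit next to the two theoretical poles computed from the same
cohort's survival rates and family sizes, the controller-share bound
translates the comparison into a population statement, and the diagnostics
panel says whether the twin labels can be trusted in the first place.
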