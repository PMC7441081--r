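# twinstest

Tools for the **twin-birth quasi-experiment** in historical demography: did
pre-industrial couples practise *parity-dependent* fertility control — that
is, did they change their childbearing once they had "enough" children?

A twin delivery is a quasi-random +1 shock to family size at a known parity.
In a population with no parity-dependent control, families experiencing a
twin birth end up with exactly **one** extra birth on average, at whatever
parity the twin arrives. In a population where every couple holds a target
number of surviving children, the twin crowds out later births and the
average extra-birth effect falls to

```
2 (1 - theta_t / theta_s) (1 - phi) + phi
```

where `theta_s` and `theta_t` are the probabilities that a singleton child
and a twin child survive to age 14, and `phi` — the chance the twin falls at
the family's last planned birth — is the reciprocal of mean births per
family. The analogous expected effects on children surviving to 14 are
`2 theta_t - theta_s` (no control) and `phi (2 theta_t - theta_s)` (complete
control). Comparing an estimated twin effect with these two poles bounds the
share of the population that could have been controlling.

The package provides, as tidyverse-style functions over per-delivery tables:

* `simulate_cohort()` / `sim_config()` / `cohort_preset()` — a monthly-step
  microsimulator of marital birth histories under natural fertility,
  target-driven stopping, or any mixture, with six presets calibrated to
  published historical samples (England, France, Québec);
* `build_analysis_table()`, `apply_filters()`, `read_cohort_csv()` /
  `write_cohort_csv()` — data model, sample-inclusion filters and CSV I/O;
* `estimate_twin_effect()`, `estimate_parity_interaction()`,
  `estimate_post_twin_interval()`, `parity_profile()` — the least-squares
  twin-effect estimators (additive or fully interacted parity-by-age
  controls, optional family-clustered standard errors), with `tidy()`,
  `glance()` and `autoplot()` methods;
* `expected_extra_births()`, `expected_extra_survivors()`,
  `controller_share_bound()`, `controller_share_probability()` — the
  closed-form poles and normal-approximation mixture bounds;
* `same_sex_diagnostic()`, `familial_repetition()`, `twinning_correlates()`,
  `corrupt_twin_labels()` — register-quality diagnostics built on the
  same-sex twin ratio;
* `run_pipeline()` / `make_report()` — an end-to-end run emitting CSV, JSON
  and a Markdown report (plus a thin CLI at `inst/scripts/twinstest`).

## Worked example

```r
library(twinstest)

res <- run_pipeline(run_config(preset = "england_pre1880",
                               n_families = 20000, seed = 1))

res$estimates$births
#> <twin_effect> extra total births per twin delivery (parametric)
#>   coefficient 1.0617  (SE 0.0489)  n = 96402

res$theory$bounds$births
#> <mixture_interval> share of controllers: point 0.000,
#>   one-sided-upper 95% interval [0.000, 0.030]

res$estimates$interval
#> <twin_effect> post-twin change in next birth interval (months) (parametric)
#>   coefficient -0.2614  (SE 0.3343)  n = 81248

res$diagnostics$same_sex
#> <twin_quality>
#>   twinning rate: 1.75 twin children per 100 births (852 pairs)
#>   same-sex ratio: observed 0.736, expected at full detection 0.728
#>   implied detection fraction: 1.033
```

Reading the output: this cohort was simulated with *no* controllers, and the
estimated twin effect on total births (1.06, SE 0.05) indeed sits at the
natural-fertility pole of 1 — far from the complete-control pole of 0.38
implied by this cohort's survival rates and its last-birth fraction of 0.16.
Inverting the mixture, at 95% confidence no more than 3% of these families
could have held a target family size. The post-twin birth interval is
unchanged (-0.3 ± 0.3 months), i.e. no spacing response either, and the
same-sex ratio of the twin pairs matches full detection (implied detection
fraction ≈ 1), so the twin labels themselves are sound.

Simulating with `controller_fraction = 1` instead drives the estimate to the
control pole; `vignette("twins-test")` documents the model, the estimators,
the simulator's assumptions, and the validation strategy in detail.

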