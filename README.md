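# flushrisk

Tools for studying deceptive nest defence in small ground-nesting shorebirds
with single-parent incubation (e.g. sandpipers and phalaropes). These birds
cannot fight off nest predators; when one approaches, the incubating bird
chooses a *flush distance* — the predator distance at which it leaves the
nest. Flushing very late and distracting the predator near the nest (active
deception) or flushing very early and leaving unseen (passive deception) can
both work; this package quantifies why distances in between are the dangerous
ones, and provides the statistical machinery used to analyse field tables of
nest records.

## The model

The risk that a flush reveals the nest is the product of two probabilities in
the threshold flush distance *d*:

```
P_detect(d):  1 for d ≤ F_close,  0 for d ≥ F_long,  declining in between
P_flush(d):   (d / r_ref)²  capped at 1
R(d) = P_detect(d) · P_flush(d)
```

with defaults `F_close = 5 m`, `F_long = 100 m`, `r_ref = 125 m` and a linear
detection decline. Short-distance flushes are rarely triggered; long-distance
flushes carry no information; the product peaks at intermediate distances —
for the linear decline at exactly `2·F_long/3 ≈ 66.7 m`. The package provides:

* `risk_params()`, `detection_probability()`, `flush_probability()`,
  `flush_risk()`, `risk_curve()`, `argmax_risk()`, `high_risk_band()` — the
  closed-form model;
* `simulate_encounters()`, `estimate_risk_curve()`, `simulate_population()`,
  `observer_discovery_filter()` — a seeded Monte Carlo encounter simulator
  (stationary-predator and walking-transect geometries) that serves as a
  brute-force check on the algebra and generates nest fates for populations
  of strategies;
* `generate_nests()`, `synthetic_preset()` — a synthetic nest-record
  generator with `paper_like`, `unimodal_null` and `bimodal_alternative`
  presets;
* `dip_statistic()`, `dip_test()` — Hartigan's dip statistic of unimodality,
  implemented in C++ from the convex-minorant/concave-majorant geometry with
  a seeded Monte Carlo uniform null;
* `fit_defence_ordinal()`, `fit_fate_logistic()`, `predicted_fate_curve()`,
  `flush_t_test()`, `linreg_r2()`, `summarize_nests()` — the analysis
  pipeline for nest-record tables;
* `read_nest_table()`, `write_nest_table()`, `write_results()` — validated
  delimited-text I/O, and a thin CLI at
  `system.file("cli", "flushrisk.R", package = "flushrisk")`.

## Worked example

```r
library(flushrisk)

p <- risk_params()                   # F_close 5 m, F_long 100 m, r_ref 125 m
argmax_risk(p)                       # 66.67  (riskiest flush distance, m)
high_risk_band(p, fraction = 0.5)    # 33.3 .. 91.1 m at half the peak risk

d <- generate_nests(synthetic_preset("paper_like", seed = 7))
summarize_nests(d)
#>    species  n mean_flush sd_flush hatch_success
#>  sandpiper 62      19.02    23.69         0.177
#>  phalarope 38      13.35    17.04         0.211
#>  ...
#>  Pooled flush-distance bin proportions:
#>    [0,5)   [5,20] (20,Inf)
#>     0.25     0.55     0.20

dip_test(d$flush_distance_m, n_null_samples = 1000, seed = 1)
#> D = 0.024, p = 0.979       (no evidence against unimodality at n = 100)

fit <- fit_fate_logistic(d)
#> beta_flush -0.2432 (se 0.0889), beta_flush_sq 0.0042 (se 0.0016)
predicted_fate_curve(fit, range = c(0, 100))$max_predation_distance
#> 28.7                        (estimated riskiest distance on this sample)
```

The summary shows the structure the generator emulates: right-skewed flush
distances around a 13–19 m mean, phalaropes overwhelmingly pure-flushing
while sandpipers escalate to distraction displays, and predation dominating
nest fate. The fate regression recovers a concave predation curve whose
maximum, on a 100-nest sample, is estimated with substantial noise around
the generating optimum.

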