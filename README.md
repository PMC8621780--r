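# gyrsurv

Bayesian mark-recapture-recovery (MRR) survival models for long-lived
raptors, built for ringing programmes like the Icelandic gyrfalcon
(*Falco rusticolus*) monitoring scheme, where live resightings are rare
and most information about survival arrives as dead recoveries of ringed
birds.

## The model

Each bird's yearly encounter code — `L` seen alive, `D` recovered dead,
`U` neither — is modelled as the emission of a three-state hidden Markov
chain (alive; recently dead, i.e. a recoverable carcass; long dead,
absorbing):

```
         | s    1-s   0   |                | p   0   1-p |
Gamma =  | 0    eta   1-eta|          O =  | 0   r   1-r |
         | 0    0     1   |                | 0   0   1   |
```

with annual survival `s` (stage-structured: juvenile rate for a
nestling's first three transitions, adult rate `s2` thereafter), carcass
persistence `eta`, live detection `p` and dead recovery `r`. Juvenile
survival can respond to yearly covariates through a logistic link:
constant (Model A), prey density `s1(t) = logistic(mu_s1 + beta * x1[t])`
(Model B, with a positive-slope threshold variant), prey plus winter
weather (Model C), or a deliberately wrong equal-rates control (Model S).
Likelihoods are computed with the forward algorithm (C++ core, identical
histories pooled); posteriors are sampled by adaptive random-walk
Metropolis on the unconstrained scale; models are compared with
bridge-sampling Bayes factors and PSIS-LOO cross-validation. A generative
simulator mirrors the model exactly, so the whole pipeline is testable
without the (non-redistributed) ringing data.

## Worked example

Simulate a full-scale study (47 years, 1,669 birds, generating values
matching published gyrfalcon estimates) and fit the constant-survival
model:

```r
library(gyrsurv)
sim <- simulate_histories(scenario_paperlike(seed = 1))
print(sim$set)
#> Capture-history set: 1669 birds, study years 1973-2019
#>   nestling-ringed: 1645, adult-trapped: 24
#>   post-marking live encounters: 31, dead recoveries: 214, birds ever re-encountered: 238

fit <- mrr_fit(sim$set, mrr_model("A"), seed = 2, warmup = 2000, iter = 4000)
summary(fit)
#>  parameter  mean    sd lower95 upper95   rhat
#>         s1 0.340 0.037   0.261   0.410 1.0109
#>         s2 0.832 0.037   0.750   0.901 1.0044
#>          p 0.028 0.007   0.017   0.044 1.0074
#>          r 0.121 0.011   0.098   0.141 1.0047
#>        eta 0.112 0.066   0.008   0.255 1.0078

mean_stage_duration(coef(fit)[["s2"]])   # expected adult-stage length
#> [1] 5.96
```

The juvenile (0.34 [0.26, 0.41]) and adult (0.83 [0.75, 0.90]) survival
posteriors bracket the generating values 0.40 and 0.83; `eta`'s wide
interval reflects how weakly carcass persistence is identified when
recoveries are this sparse (see the methods vignette). `predict(fit)`
returns the posterior juvenile-survival curve over a prey-density grid,
`plot(fit)` draws it, and for several models

```r
run_pipeline(list(output_dir = "out", models = c("A", "B", "S"),
                  simulate = "paperlike", seed = 1))
```

writes posterior summaries, an R-hat table, a Bayes-factor matrix, a
PSIS-LOO table, the survival-vs-prey curve and a machine-readable
`report.json`.

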