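# twotone

Pipelines for two-tone (Mooney) image experiments: stimulus synthesis,
image statistics, touchscreen response scoring, synthetic-cohort
simulation, and multilevel inference.

## The problem this package addresses

Two-tone images are grayscale photographs degraded by Gaussian smoothing
(SD σ, in pixels) followed by luminance binarization at a threshold θ:

    T(x, y) = 255 · 𝟙[ (G_σ * I)(x, y) > θ ]

They are often unrecognizable at first sight, yet become vividly
recognizable after a single glance at the source photograph — *perceptual
reorganization*, the effect of prior knowledge on perception.
Developmental studies of this effect present two-tones on a touchscreen,
cue with the grayscale, and ask participants to name image content and
point at prompted object features; analysis then needs ROI-based scoring,
trial exclusion rules, an error taxonomy, and crossed-random-effects
models. This package gives researchers in visual psychophysics and
developmental vision the whole chain as seeded, tested R code, plus a
synthetic behavioral cohort generator so every stage can be validated
without participant data.

The statistical core is the multilevel logistic model with crossed random
intercepts for participants and images,

    logit P(correct_{pi} = 1) = μ_{age(p)} + γ·recognized_{pi}
                                + (γ×age interactions) + u_p + v_i (+ w_roi),
    u_p ~ N(0, σ_p²),  v_i ~ N(0, σ_i²),

fitted with lme4, with age trends tested by likelihood-ratio tests against
reduced models, pairwise age contrasts by Wald z (adult reference), a
Gaussian mixed model on log pointing distance, percentile-bootstrap CIs
for group means, and Pearson imagewise correlations. Low-level image
structure is summarized by Sobel edge density and by contrast energy (CE)
and spatial coherence (SC) — the Weibull scale and shape of
centre-surround (parvo/magno-like) contrast distributions.

## Worked example

Simulate a small two-group cohort, score it, and test the age effect on
naive two-tone naming:

```r
library(twotone)

cfg <- cohort_config(group_sizes = c(12, 10),
                     group_labels = c("4-5y", "adult"), seed = 42)
sim <- simulate_cohort(cfg)
#> simulated cohort: 22 participants (12/10), 528 trials

scored <- score_trials(sim$trials, sim$rois,
                       make_synthetic_scheme(unique(sim$trials$image_id)))
kept <- apply_exclusions(scored)

naming <- kept$naming[!kept$naming$is_catch, ]
naming$correct <- as.numeric(naming$naive_correct)
fit  <- fit_mixed_logistic(naming, model_spec("correct", "age_group"))
null <- fit_mixed_logistic(naming, model_spec("correct", character(0)))
fit
#> multilevel logistic fit: correct ~ age_group + (1 | participant_id) + (1 | image_id)
#>   n = 435, logLik = -273.40 (df 4), converged: TRUE
#>           term estimate    se      z      p
#>    (Intercept)  -0.0381 0.332 -0.115 0.9087
#>  age_group4-5y  -0.7768 0.430 -1.808 0.0706

lrt(fit, null)
#> LRT: X2(1) = 3.05, p = 0.0807

aggregate_performance(kept$naming, "age_group", "naive_accuracy")
#>   age_group      mean
#> 1      4-5y 0.3403361
#> 2     adult 0.4923858
```

Reading the output: 435 experimental trials survive the exclusion rules
(grayscale naming failures leave all analyses). Young children name about
34% of the two-tones naively, adults about 49%; the age coefficient is
−0.78 log-odds against the adult reference, and at this toy sample size
the age effect does not reach significance (Χ²(1) = 3.05, p = 0.08) —
at the full design size (31/23/18/13 participants) the same effect is
highly significant, as `run_pipeline()` shows.

`run_pipeline(pipeline_config(seed = 1), "out/")` runs the whole chain —
synthetic stimuli, image statistics, full four-group cohort, scoring,
and every analysis of the design (naming LRT and contrasts,
recognized-by-age reorganization tests for pointing accuracy and log
distance, local/global error taxonomy, bootstrapped group means,
imagewise correlations) — into a directory with a config and a seeded,
hash-stamped manifest; repeated runs are byte-identical.

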