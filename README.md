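# framecast

Categorical dynamic Bayesian networks for tailoring framed health
messages.

`framecast` is for biostatisticians and behavioral-intervention
researchers who run two-wave randomized message-framing studies — here,
messages recommending reduced red/processed-meat consumption, framed as
*gain*, *non-loss*, *non-gain* or *loss* along the outcome-sensitivity
axis — and want to (a) learn which psychosocial antecedents drive the
change in intention after message exposure, and (b) predict, for any
receiver profile, which framing would move them most.

## What it computes

The core object is a three-slice categorical dynamic Bayesian network
(Time 1 → message → Time 2) over the study's discretized scales, with the
five-category intention change `Z` as target, factorized as
`p(X1,…,Xn) = Πᵢ p(Xi | π(Xi))` and fit with Laplace-smoothed CPTs.
Structure is elicited automatically: parent sets are screened per node by
empirical information gain `IG(X; S) = H(X) − H(X|S)`, the retained sets
are crossed into a candidate pool, and each candidate `i` is scored by

    m⁽ⁱ⁾ = mAUCin⁽ⁱ⁾ / maxⱼ mAUCin⁽ʲ⁾ + mAUCout⁽ⁱ⁾ / maxⱼ mAUCout⁽ʲ⁾

where mAUC is the Hand–Till multiclass AUC of the exact class posteriors,
in-sample and via leave-one-out. Because the message node is randomized
(parentless), the Time-1 variables are a valid adjustment set and the
fitted network reads as a graphical causal model: the average potential
effect (APE) of framing `m` for a profile `T1ₒ` is

    E[Y(m) | T1ₒ] = Σ_z w(z) Σ_{T1ₙ} p(z | m, T1ₒ, T1ₙ) p(T1ₙ)

with utility weights `w = (2, 1, 0, −1, −2)` over the ordered
intention-change categories. Enumerating every Time-1 configuration
(3⁸ = 6561 individuals for the reference network) attaches a 4-vector of
framing APEs to each simulated receiver; Euclidean dissimilarity on these
vectors supports soft clustering, t-SNE visualization, and extraction of
2%-quantile receiver prototypes (per-framing best responders, the
*indifferent*, and the *oppositive*).

A calibrated synthetic cohort generator (Time-1 scale means/SDs, 4-arm
randomization, the study's eligibility filter, configurable ground-truth
causal structure) stands in for the questionnaire data, so every stage is
testable end to end.

## A worked example

```r
library(framecast)

cfg    <- cohort_config(seed = 42)        # study conditions: n = 834, Table-1 calibration
cohort <- simulate_cohort(cfg)
kept   <- apply_exclusions(cohort)
kept$counts
#> special_diet     low_meat   incomplete
#>          142          102           63       (527 survivors)

vars <- c("baseline_intention","prevention_focus","perceived_severity",
          "diffused_responsibility","promotion_focus","food_involvement",
          "perceived_behavioral_control","desensitization",
          "systematic_processing","delta_intention")
map  <- fit_discretization(kept$cohort[vars])     # 33% / 20% quantile cuts
disc <- apply_discretization(kept$cohort[c(vars, "condition")], map)

fit <- framing_dbn(disc, structure = rpmc_network())
fit
#> Message-framing dynamic Bayesian network
#>   11 variables, 11 arcs; n = 527; alpha = 1
#>   mAUC in-sample 0.9521 | leave-one-out 0.6884
#>   outcome: delta_intention | parents: condition, systematic_processing,
#>   baseline_intention, prevention_focus, perceived_severity, diffused_responsibility

t1 <- c(baseline_intention = "high", prevention_focus = "high",
        perceived_severity = "high", diffused_responsibility = "low",
        promotion_focus = "medium", food_involvement = "medium",
        perceived_behavioral_control = "medium", desensitization = "low")
effect_vector(fit, t1)
#> Effect vector: gain=-0.2540  nonloss=-0.2540  nongain=-0.0667  loss=-0.0833
#>   mean -0.1645 | best -0.0667 (nongain) | delta 0.0978

profile <- profile_population(fit)        # all 6561 Time-1 profiles
extract_prototypes(profile, q = 0.02)
#> Receiver prototypes (132 individuals per group, q = 0.02)
#>   best-gain      n= 132  modal: baseline_intention=low, prevention_focus=high, ...
#>   ...
```

Reading the numbers: the in-sample mAUC (0.95) far exceeds the
leave-one-out mAUC (0.69), the usual optimism gap the selection metric is
built to balance. The effect vector says that for this strongly
prevention-focused, severity-aware profile every framing has a mildly
negative expected utility under the printed weight convention (positive
weights reward *increased* meat intention; see
`utility_weights(negate = TRUE)`), with *non-gain* the pivot and a delta
effect of 0.10 utility points separating the best framing from the
average one. Each prototype group holds exactly ⌈0.02 × 6561⌉ = 132
receivers summarized by their modal antecedents. Numbers shown are from
this synthetic cohort (seed 42); structure elicitation
(`framing_dbn(disc, variables = study_variables(...))`) instead of the
fixed reference structure takes a few seconds at this scale.

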