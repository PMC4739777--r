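# hetpop — population heterogeneity analysis for trial-based calcium imaging

`hetpop` analyses trial-structured two-photon calcium imaging recorded
while an animal performs a visual go/no-go detection task, and asks which
aspect of the single-trial population state correlates with detection. Its
core statistic is **population heterogeneity**: for trial *t*, z-score each
neuron's mean stimulus response over all trials,
`Z[i,t] = (R[i,t] − μ_i)/σ_i`, and take the mean absolute pairwise
difference over all neuron pairs,

    h_t = Σ_{i<j} |Z[i,t] − Z[j,t]| / (n(n−1)/2),

i.e. how *dissimilarly* the population was activated on that trial,
independent of overall level. An equivalent geometric form — the Euclidean
distance from the trial's population vector to the all-equal diagonal of
neural response space — correlates with `h_t` at r > 0.9 and supports
mirroring and mean/heterogeneity-removal analyses.

Around the metric, the package implements the full analysis battery:
hit-modulation decomposition with shuffle nulls, pooled-SD Cohen's d and
rank-statistic ROC AUC per contrast, reaction-time regressions, 10–90%
rise times, pre-stimulus predictability (leave-one-out δ), inter-trial
pattern consistency, noise correlations, Clopper–Pearson behavioural
intervals, Benjamini–Hochberg FDR, leave-one-out Gaussian naive-Bayes
decoders (stimulus presence, orientation, 21-way stimulus type, and
single-trial prediction of the upcoming response type), and response-space
geometry. A synthetic session generator emulates the task (8 directions ×
6 contrasts in randomised 48-trial blocks, contrast-dependent psychometric
behaviour, arousal-linked reaction times) so the entire pipeline runs,
calibrates and validates without external data.

Audience: systems/computational neuroscientists analysing trial-aligned
dF/F population recordings from detection tasks, and anyone needing a
tested reference implementation of the heterogeneity statistic and its
comparators.

## Worked example

```r
library(hetpop)

# a synthetic session under the default (effectful) generative model
gen <- generate_session(synth_config(seed = 1))
cfg <- analysis_config(rng_seed = 1)

dff <- compute_dff(gen$session$soma, gen$session$frame_rate)
rsp <- extract_trial_responses(gen$session, dff, cfg)
z   <- zscore_responses(rsp, "global")

het  <- heterogeneity(z)            # one value per trial, SD units
mdff <- colMeans(rsp$values)        # mean population dF/F0 per trial

attr(roc_by_contrast(het,  rsp), "mean_auc")
#> [1] 0.7892247
attr(roc_by_contrast(mdff, rsp), "mean_auc")
#> [1] 0.6054937
regress_metric_on_rt(het, rsp)$slope
#> [1] -0.2887114
```

Heterogeneity separates hit from miss trials (mean ROC AUC 0.79 over the
test contrasts 0.5–32%) clearly better than the mean population dF/F0
(0.61), and higher-heterogeneity trials have faster reaction times
(negative regression slope) — the qualitative result pattern the pipeline
is designed to detect, here recovered from a session whose generative
parameters are known.

The numbered drivers under `analysis/` run the complete workflow on a
simulated session (`01_simulate_session.R` → `07_geometry.R`), printing
what each stage found and writing its tables under `results/`.

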