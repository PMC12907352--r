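# playseq

Behavioral-sequence analysis of structured play observation in autistic and
typically developing children.

Coded play sessions produce *event streams*: timestamped sequences of social
behaviors (nonverbal initiation, responsive behavior, emotional sharing,
joint attention, speech initiation, avoidance, stereotypy). `playseq` is for
researchers who want to analyze the *organization* of those streams rather
than raw behavior counts:

* **Lag-sequential analysis** — transition counts and the row-stochastic
  conditional matrix `P(j|i) = N(i→j)/N(i)`, multi-step transitions
  `λ^T P^T`, stationary distributions, cyclicity/transitivity.
* **Sequence complexity** — Shannon entropy (bits) of the lag-1 bigram
  distribution, `H = −Σ p(x) log₂ p(x)`; average sequence length over
  gap-delimited interaction episodes; frequent behavior-chain mining.
* **Preprocessing and reliability** — event merging at a 0.5 s interval,
  per-category minimum durations, Cohen's κ and the absolute-agreement
  ICC for coder reliability.
* **Physiological coupling** — causal moving-average smoothing, behavior
  indicator rasterization, normalized cross-correlation `CC(τ)` with
  per-lag overlap statistics, and event-locked pre/post contrasts.
* **Latent class analysis** — the K-class mixture of independent Bernoulli
  indicators `P(x) = Σ_k π_k Π_i θ_ik^{x_i}(1−θ_ik)^{1−x_i}`, estimated by
  multi-restart EM; BIC/AIC/classification entropy; adjusted and bootstrap
  likelihood-ratio tests; two-stage class-count selection.
* **Clinical association** — the ≥20%-reduction responder rule,
  class-stratified response rates, logistic odds of response,
  covariate-adjusted (ANCOVA-style) contrasts, and bootstrap mediation of
  class effects through behavioral entropy.
* **A seeded synthetic cohort generator** that emulates the study's
  statistical structure (latent classes 0.35/0.40/0.25, group transition
  kernels, entropy-calibrated sequences, event-locked HRV deflections,
  graded responder rates 0.68/0.42/0.19) so every stage is testable end to
  end with known ground truth.

## Worked example

Recover a three-class structure from synthetic indicator data and stratify
intervention response by class:

```r
library(playseq)
set.seed(505)
th  <- default_indicator_theta()                    # planted class profiles
cls <- sample(colnames(th), 300, TRUE, prob = c(.35, .40, .25))
X   <- generate_indicators(cls, th)                 # binary children x indicators

sel <- select_classes(X, kmin = 2, kmax = 5, restarts = 20, seed = 9)
sel$table[, c("k", "bic", "aic", "rel_entropy", "lmr_p")]
#>  k  bic  aic rel_entropy     lmr_p
#>  2 2499 2444      0.8481 8.203e-51
#>  3 2458 2373      0.7962 4.241e-15
#>  4 2489 2374      0.8425 8.013e-02
#>  5 2525 2380      0.8202 2.868e-01
sel$chosen_k
#> 3

m    <- sel$models[["k3"]]
perm <- match_labels(m$theta, th)                   # undo label switching
round(m$pi[perm], 3)                                # high / medium / low
#> 0.344 0.450 0.205   (empirical truth: 0.353 0.413 0.233)

out <- generate_outcomes(cls)                       # planted responder rates
rr  <- response_rates(out$class,
                      response_flags(out$ados_baseline, out$ados_post))
rr[match(c("high", "medium", "low"), rr$class), ]
#>   class responders total rate
#>    high         76   106   72
#>  medium         50   124   40
#>     low         15    70   21
```

BIC bottoms out at k = 3 with likelihood-ratio support (p < 0.001 for 3 vs
2, none for 4 vs 3), the matched mixing proportions land within sampling
error of the planted 35/40/25 split (estimates at n = 300 carry a standard
deviation of about 4 percentage points), and the per-class response rates
grade from 72% down to 21% around the planted 68/42/19.

Sequence-level metrics work directly on event logs:

```r
cohort <- generate_cohort(cohort_config(seed = 42))  # 60 ASD + 40 TD children
ab  <- behavior_alphabet()
grp <- cohort$truth$group[match(cohort$log$child_id, cohort$truth$child_id)]
asd <- event_log(as.data.frame(cohort$log)[grp == "ASD", ], ab)
td  <- event_log(as.data.frame(cohort$log)[grp == "TD", ], ab)
average_sequence_length(asd)   #> 4.2 events/episode
average_sequence_length(td)    #> 6.5
head(as.data.frame(mine_chains(td, min_support = 0.5)), 2)
#>                                     chain count probability support
#>   nonverbal_initiation -> joint_attention   582       0.555       1
#>  responsive_behavior -> speech_initiation   576       0.529       1
```

The autistic group's shorter episodes and the typical group's modal
initiation → joint-attention chain (planted at 0.56) are both recovered.
`run_pipeline()` chains preprocessing → transitions/metrics → optional
coupling → LCA selection → clinical association and writes CSV/TSV tables
plus a JSON report whose config echo suffices to rerun the analysis.

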