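---
title: "Modeling social behavior sequences from structured play observation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling social behavior sequences from structured play observation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(playseq)
```

## The problem

Coded observation of structured play yields an *event stream*: a timestamped
sequence of social behaviors (nonverbal initiation, responsive behavior,
emotional sharing, joint attention, speech initiation, avoidance, and
optionally stereotypy) for each child and session. Static frequency counts
discard the temporal organization of that stream. `playseq` analyzes the
stream itself along four axes:

1. **Lag-sequential structure** — the conditional probability
   $P(j \mid i) = N(i \to j) / N(i)$ that behavior $j$ immediately follows
   behavior $i$, assembled into a row-stochastic transition matrix, with
   multi-step extensions $\lambda^T P^T$ that discount longer horizons.
2. **Sequence complexity** — the Shannon entropy (bits) of the empirical
   distribution of behavioral units, the average number of events per
   interaction episode (ASL), and the cyclicity/transitivity split of the
   transition matrix.
3. **Latent heterogeneity** — a $K$-class mixture of independent Bernoulli
   indicators,
   $P(x) = \sum_k \pi_k \prod_i \theta_{ik}^{x_i}(1-\theta_{ik})^{1-x_i}$,
   fitted by EM, with BIC/AIC, classification entropy, and adjacent-model
   likelihood-ratio tests used to choose $K$.
4. **Clinical coupling** — physiological cross-correlation and event-locked
   contrasts, responder stratification by latent class, logistic odds of
   response, covariate-adjusted group contrasts, and entropy-mediation of
   class effects.

Because no raw cohort accompanies the design, the package ships a seeded
synthetic cohort generator that emulates the statistical structure these
analyses assume. Every analysis stage is exercised end to end on generated
cohorts with known ground truth; the test suite and `scripts/acceptance.R`
score recovery of the planted parameters.

## Choices with scientific content

### Entropy support

Unigram entropy over six categories is bounded by $\log_2 6 \approx 2.585$
bits, which cannot accommodate the typical-development group means the
analysis is designed to detect (about 3.1 bits). The default support is
therefore the **lag-1 bigram distribution** (ordered pairs of consecutive
behaviors, at most $K^2$ cells, bounded by $\log_2 36 \approx 5.17$ bits),
with unigram entropy available as an option. Bigram entropy is also the more
faithful reading of "sequence diversity": it measures the variety of
behavior-to-behavior transitions, not just the marginal behavior mix.

### Multi-step transitions

The $T$-step law is implemented as the Chapman–Kolmogorov power $P^T$ scaled
by a per-step decay weight $\lambda^T$ ($0 < \lambda \le 1$). At $T = 1$,
$\lambda = 1$ this is exactly the lag-1 matrix, the primary analysis case;
the decay factor encodes the weakening of behavioral dependence over longer
horizons without inventing a new stochastic process.

### Episodes and average sequence length

Interaction episodes are delimited wherever the gap between consecutive
events exceeds a threshold (default 5 s, configurable). ASL is the mean
number of events per episode. The threshold sits well above the 0.5 s
merge interval used in preprocessing, so episode segmentation and event
merging cannot interact.

### Preprocessing order

`segment_events()` first merges same-category events separated by less than
0.5 s, then drops events shorter than their category's minimum codable
duration. Merging first means a long behavior fragmented by sub-threshold
coding gaps survives the duration filter; the operation is idempotent and
never increases total coded time.

### The LMR approximation

`lmr_test()` defaults to the ad hoc adjusted likelihood-ratio approximation:
$2\Delta LL$ shrunk by $1/(1 + 1/(d \log n))$ and referred to $\chi^2_d$.
This mirrors common practice but is known to be anticonservative at mixture
boundaries (the regularity conditions for the $\chi^2$ reference fail
there). The parametric bootstrap variant (`variant = "bootstrap"`) refits
both models on data simulated under the smaller model and is the robust
choice when runtime permits. Model selection therefore leads with BIC and
uses the LMR p-value only as the two-stage tie-breaker: the BIC minimizer is
stepped down one class when its own test is unsupportive while the smaller
solution's test is supportive.

### EM numerics

Responsibilities are computed with log-sum-exp; $\theta$ is floored at
$10^{-6}$ from both ends; 20 random restarts by default, best log-likelihood
kept; classes are reported in decreasing mixing-proportion order, and
`match_labels()` resolves label switching exhaustively for recovery studies.
Convergence uses a *relative* log-likelihood criterion
($\Delta LL < \mathrm{tol}\,(|LL| + \mathrm{tol})$): when the scanned class
count exceeds the true one, the likelihood ridge is nearly flat and absolute
increments decay geometrically but remain above any tiny absolute cutoff for
thousands of iterations; the relative criterion terminates these fits
without affecting well-separated ones (the increments at termination are
orders of magnitude below the BIC differences that drive selection).

### Indicator dichotomization

The mixture likelihood is defined on binary indicators, while observed
inputs are behavior frequencies. `binarize_indicators()` dichotomizes each
indicator at its median by default (ties low), with a z-score-at-zero rule
and explicit thresholds as alternatives; the rule and per-column thresholds
are recorded on the returned matrix. A Gaussian-mixture treatment of the
standardized frequencies is deliberately out of scope.

### Coupling conventions

The cross-correlation between an HRV-like series and a binary behavior
indicator recomputes mean, variance and correlation on the overlapping
region at every lag, so $|CC(\tau)| \le 1$ holds for all lags and no edge
padding is invented. Positive $\tau$ means the behavior sample trails the
physiological sample; a physiological response that *follows* behavior
onsets therefore peaks at negative $\tau$. Moving-average smoothing is
causal with partial-window normalization (output length equals input
length; `M = 1` is the identity; constants are preserved). HRV is consumed
as a precomputed series — R-peak detection from raw ECG is out of scope.

## The synthetic cohort generator

`generate_cohort()` draws, per child:

* a latent class from mixing proportions 0.35 / 0.40 / 0.25 (ASD) or the TD
  profile;
* interaction episodes with lengths $1 + \mathrm{Poisson}(\mu - 1)$ around
  the class episode mean (4.2 events for ASD profiles, 6.8 for TD), episodes
  separated by super-threshold gaps and events within an episode by gaps in
  $[0.6, 2]$ s — above the merge interval and below the episode threshold,
  so generated logs pass `segment_events()` unchanged by construction;
* behavior categories from the class transition kernel, with per-child
  Dirichlet jitter (concentration 200) around the class kernel to represent
  between-child variability the design implies but does not quantify;
* event durations as category minimum plus an exponential excess (mean one
  second above the minimum by default);
* an HRV-like signal: baseline plus an additive deflection of fixed latency
  and duration locked to a chosen behavior's onsets plus Gaussian noise —
  the simplest ground truth the coupling analysis can detect, a stand-in
  rather than a physiological model;
* binary LCA indicators $x_i \sim \mathrm{Bernoulli}(\theta_{ik})$; and
* clinical records in which responders drop 25% of their baseline total and
  non-responders 10%, so the 20% responder rule classifies every generated
  record unambiguously after integer rounding; class responder
  probabilities default to 0.68 / 0.42 / 0.19.

All draws descend from one root seed; identical configurations are
byte-identical.

### Group kernels

The 6-category ASD group kernel is the published group-level transition
profile row-normalized (only its nonverbal-initiation row is stochastic as
printed and is kept verbatim). The TD kernel is constructed so its modal
transitions are initiation → joint attention (0.56) and responsive behavior
→ speech (0.49). The 7-category kernel plants the avoidance → stereotypy
loop at exactly 0.42 with every other row maximum at 0.35, so that the
planted loop is the uniquely top-ranked chain; its remaining structure is
synthetic and carries no empirical claim.

### Indicator profiles

`default_indicator_theta()` spans the full behavioral profile — the coded
social behaviors plus interaction maintenance, seven indicators in all.
Anchored cells (high: initiation .78, responsive .65, joint attention .52,
avoidance .19; medium: initiation .41, stereotypy .62, maintenance .34;
low: avoidance .78, joint attention .12) are kept verbatim; free cells are
fixed so each class has a simple-structure signature — in particular the
medium class is marked by a stereotypy spike neither outer class shares.
This matters statistically: with graded profiles that lie *between* the
outer classes, a two-class mixture reproduces the three-class cell
distribution almost exactly (population analysis puts the expected
log-likelihood-ratio advantage of the true three-class model near 4, far
under the BIC penalty of ~40 at $n = 300$), and no estimator could select
three classes. Four indicators alone are insufficient for a second reason:
a saturated 4-indicator binary table has 15 degrees of freedom against 14
parameters for three classes, leaving the mixture practically
unidentifiable. With the seven spiked profiles the expected
likelihood-ratio advantage is well above the BIC penalty, selection
succeeds in the large majority of replicates, and the average
classification entropy (~0.75–0.8) approaches the quality the design
reports. Mixing-proportion estimates at $n = 300$ still carry a standard
deviation near 4 percentage points — the irreducible combination of
multinomial sampling and soft class boundaries — which is the dominant
uncertainty in the proportion-recovery experiments.

### Entropy calibration

`calibrate_entropy_kernel()` returns a kernel on the mixing path between a
2-state cycle (stationary bigram entropy exactly 1 bit) and the iid-uniform
kernel ($2\log_2 K$ bits), calibrated by root finding after a monotonicity
check. Two targets are supported:

* the **asymptotic** stationary bigram entropy (default, within 0.01 bit);
* the **expected plug-in entropy at a finite sequence length**
  (`n_events`), matched by bisection against seeded simulation.

The distinction matters because the plug-in entropy estimator is biased low
by roughly $(m - 1)/(2N\ln 2)$ bits ($m$ occupied cells, $N$ pairs): at 200
events per child the bias is 0.08–0.12 bits, larger than the 0.05-bit
tolerance used in the recovery experiments. Since empirical group means are
themselves finite-session plug-in values, cohort emulation calibrates at
the session scale (200 events), while the asymptotic mode remains the
mathematically clean default.

## Problem sizes and what the tests show

The recovery experiments run at the emulated study scale: $n = 300$
children for mixture recovery (20 restarts; 20 replicate cohorts for the
selection-rate check), 10,000 events for transition recovery, 60/40
children × 200 events for entropy and chain recovery. At these sizes the
suite completes in a few minutes on one core.

Passing tests demonstrate *internal* consistency — the pipeline recovers
what the generator plants, at pre-stated tolerances — not external
validity. The generator's known simplifications: behavior streams are
first-order Markov within episodes (real streams have longer memory and
non-stationarity across tasks), physiological coupling is an additive
fixed-latency box deflection, indicators are conditionally independent
given class exactly (the mixture's own assumption), and clinical scores
have no item structure. Quantities printed in the underlying design that
are not computable from available information (absolute BIC values,
adjusted odds ratios, mediation coefficients from raw data we do not have)
are *not* targets; where a published statistic disagrees with its own
printed inputs (group t statistics, the responder-table chi-square), the
package reports the value recomputed from the inputs.

## Known limitations

* The LMR approximation's p-values should be treated as heuristic near
  $K$-boundaries; use the bootstrap for decisions that depend on them.
* Chain mining ranks by conditional probability given the chain's first
  state; rare antecedents can rank high on small cohorts — the
  `min_support` filter (fraction of children exhibiting the chain) is the
  guard and should not be set to zero on small samples.
* The entropy calibration path covers $[1, 2\log_2 K]$ bits; targets below
  1 bit would require a different kernel family.
* No multiple-testing correction is applied anywhere, by design parity with
  the analysis plan the package implements; interpret families of p-values
  accordingly.
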