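---
title: "Methods: admission-blood RNA panels for stroke triage"
author: "strokeTriage authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: admission-blood RNA panels for stroke triage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`strokeTriage` implements a complete, reproducible pipeline for deriving
small blood-transcript panels that triage suspected stroke at hospital
admission. The clinical questions form a cascade of four binary tasks:

1. **Hemorrhagic vs everything else** — rules thrombolysis in or out.
2. **Ischemic vs stroke mimic** — run only on stage-1 negatives.
3. **Thrombolysis window** — onset within 3.5 h (the 4.5 h guideline minus a
   60-minute door-to-needle target), run only on ischemic calls.
4. **Severity** — NIHSS ≥ 5 vs minor, run only on ischemic calls.

Each task is served by a 3–5-transcript panel scored by a Gaussian-emission
hidden Markov model (HMM) whose posterior state probability is thresholded
at a Youden-optimal cutoff. Because real patient cohorts of this kind sit
behind controlled access, the package ships a calibrated synthetic cohort
generator so every claim is testable end to end.

```{r, eval = FALSE}
library(strokeTriage)
cfg <- simulationConfig(seed = 1L)
study <- simulateStudy(cfg)
ns <- normalizeStudy(study)
```

# Synthetic cohort generator

Counts are negative binomial with mean $\mu$ and variance
$\mu + \phi\mu^2$ (`nb_dispersion` $\phi$, default 0.15). Per-transcript
baselines are drawn log-normal (`baseline_log_mean` 6, `baseline_log_sd`
1.5); per-sample library sizes vary log-normally and two batches receive a
log-scale offset. The default cohort emulates a realistic admission-cohort
class mix (13 hemorrhagic, 29 ischemic, 42 mimic).

Three kinds of structure are planted with disjoint transcript sets:

- **Class signatures**: `signature_log2fc` (default 1.5) added to each
  class's signature transcripts; values below $\log_2 1.5$ are rejected at
  configuration time because downstream significance filtering could never
  recover them.
- **Time-correlated transcripts**: in ischemic samples, log-scale
  expression drifts linearly with onset time.
- **Severity-correlated transcripts**: expression tracks NIHSS in all
  stroke samples.

Slopes are stated in residual-SD units so their observable effect is
scale-free. For a slope of $h$ residual SDs per unit of a target with
standard deviation $s$, the expected Pearson correlation is

$$ r = \frac{h\,s}{\sqrt{1 + h^2 s^2}}, $$

and the defaults (`time_slope_sd_units` 0.17, `severity_slope_sd_units`
0.08) were chosen by inverting this formula so planted time transcripts
land mostly in $r \in [0.5, 0.95]$ at realistic cohort sizes. The residual
SD of log2 counts is approximated by the delta method as
$\sqrt{1/\mu + \phi}/\ln 2$.

Limitations: the generator has no gene-gene correlation structure, no
cell-type composition effects, and treats batch as a pure location shift;
it is a calibration instrument, not a biological simulator.

# Preprocessing

Ordered, named exclusion rules (transient ischemic attack, unknown
diagnosis, low read depth) annotate each removed sample with the first rule
that matched. Library normalization is trimmed-mean-of-M-values (TMM) via
`edgeR::calcNormFactors`; the unit tests verify it against an independent
re-implementation of the published algorithm. Log2-CPM uses a 0.5 prior
count; optional batch adjustment is per-transcript location-scale
standardization to the grand mean and pooled SD.

# Differential expression and signature sets

`differentialExpression` fits per-transcript ordinary least squares of
log2-CPM on group membership plus covariates (optionally weighted by
Mahalanobis full-matching weights from `mahalanobisMatch`), with two-sided
t-tests and Benjamini–Hochberg q-values. A transcript is *significant* at
raw $p < 0.05$ and $|\mathrm{log2FC}| \ge \log_2 1.5$.

A condition's signature set is defined as the transcripts significant and
sign-concordant in **both** of that condition's pairwise contrasts (e.g.
hemorrhagic-vs-ischemic and hemorrhagic-vs-mimic for the hemorrhagic set).
This intersection-of-contrasts design was chosen over a union because with
three classes every two-class contrast mixes two signatures; the union
makes the per-condition lists overlap so heavily that condition-unique sets
become empty, whereas the intersection recovers planted signatures at
97–100% in the test suite while keeping the unique sets disjoint.

# Gaussian-emission HMM

Panels are scored by a K-state HMM with diagonal Gaussian emissions fitted
by EM. Two modes share one code path:

- `per_sample` (default): each sample is a length-1 sequence, so the model
  degenerates to a Gaussian mixture; the transition matrix is frozen
  uniform and excluded from the BIC parameter count,
  $p_{\mathrm{free}} = (K-1) + 2KD$.
- `concatenated`: full Baum–Welch with scaled forward–backward recursions;
  $p_{\mathrm{free}}$ adds $K(K-1)$ transition parameters.

Numerical choices: log-space emission densities with a log-sum-exp
reduction, per-step scaling in the forward pass, a variance floor of
`1e-6`, and a hard error if the log-likelihood ever decreases beyond
round-off — EM monotonicity is treated as an invariant, not a hope. The
best of `nRestarts` (default 10) quantile-sliced-plus-jitter
initializations wins; all randomness flows from one integer seed, so fits
are bit-reproducible. `selectStates` picks K by BIC
($-2\log L + p_{\mathrm{free}}\ln n$), ties to the smaller K; the default
task model uses K = 2 (a case state and a control state).

The forward–backward code is tested against exhaustive state-path
enumeration (all $K^T$ paths) to 1e-10, and the per-sample posterior
against the closed-form mixture responsibility.

# Panel search

`searchPanels` chains four steps, each exported for standalone use:

1. `screenSingleTranscripts` fits a one-dimensional HMM per candidate and
   keeps transcripts whose hard training-set calls reach `accuracyFloor`
   (default 1, the perfect-separation rule). Screening fits use lighter EM
   settings (3 restarts, 150 iterations, tol 1e-5) because the pass rule
   depends on hard calls, not refined likelihoods.
2. `enumeratePanels` lists all subsets of sizes 3–5 and *refuses* (rather
   than silently subsampling) when the closed-form count exceeds 250,000.
3. `evaluatePanel` is strictly training-frozen: the HMM fit, the
   majority-vote state-to-class map, and the Youden-optimal posterior
   threshold (midpoints of adjacent sorted unique posteriors; ties to the
   smallest) are all determined on training data before validation samples
   are ever scored. A dedicated test perturbs validation data and asserts
   the frozen model is bit-identical.
4. `selectRepresentative` applies a deterministic ladder: maximal
   min(train, validation) accuracy → widest separating posterior gap
   (threshold stability) → fewest transcripts → fewest unannotated `MSTRG`
   IDs → lexicographically smallest ID tuple.

# Cascade and audit

`runCascade` applies the frozen stage-1 model to every sample, stage 2
only to stage-1 negatives, and the window/severity models only to samples
called ischemic (`conditional = FALSE` scores them on everyone for
research use). Metrics with an empty denominator are `NA`, never silently
zero, so an all-negative held-out cohort reports specificity 1 and an
*undefined* sensitivity. `heldOutAudit` wraps the cascade for cohorts
disjoint from training and tolerates absent classes and empty cohorts.
`writeTriageReport` serializes per-sample calls as TSV and cohort metrics
as JSON.

# Reproducibility

Every stochastic step takes an explicit integer seed and uses
`withr::with_seed`, so the full pipeline — simulate → normalize → select →
search → cascade — is bit-reproducible. `scripts/acceptance.R` runs the
whole pipeline from a single `--seed` and writes the headline quantities
as JSON; the test suite pins worked examples, brute-force oracles
(forward–backward, TMM, Benjamini–Hochberg, Pearson) and property-based
recovery bounds with fixed seeds and no environment gating.
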