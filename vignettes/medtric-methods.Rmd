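---
title: "Clinically aligned scoring of multi-label diagnostic systems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clinically aligned scoring of multi-label diagnostic systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medtric)
```

## The problem

A multi-label diagnostic system reads one sample (an ECG, a radiograph, a
clinical note) and emits a *set* of diagnosis codes drawn from a finite
catalog. Judging such a system with metrics borrowed from general machine
learning ignores facts that are close to axiomatic in clinical practice:

* a **wrong diagnosis** (prediction disjoint from the truth) is worse than a
  **missed diagnosis** (prediction a proper subset of the truth), which is in
  turn worse than an **over-diagnosis** (truth a proper subset of the
  prediction);
* some diagnoses matter more than others;
* some diagnoses are mutually contradictory and predicting both should be
  disqualifying;
* the verdict on a system should not depend on how common each condition
  happens to be in the evaluation sample.

This package implements a score built around those requirements, the standard
label-based and example-based multi-label metrics it is compared against, and
two Monte-Carlo stress tests that probe any metric for clinical-order
violations and prevalence sensitivity.

## The score

Let the catalog hold $P$ codes, let $y_i$ and $\hat z_i$ be the truth and
prediction sets of instance $i$, and let $n_j$ count the instances whose truth
contains code $j$ (prevalence, computed from truths only). With significance
weights $s_j > 0$ and a similarity matrix $w$ ($w_{jj} = 1$,
$0 < w_{jk} < 1$ off the diagonal), code $j$ contributes to instance $i$:

$$a_i(j) = \begin{cases}
 +s_j/n_j & j \in \hat z_i \cap y_i \quad\text{(correct)}\\[2pt]
 -s_j/n_j & j \in y_i \setminus \hat z_i \quad\text{(missed)}\\[2pt]
 \dfrac{s_j}{n^*}\Bigl[\dfrac{1}{|y_i|}\sum_{k \in y_i} w_{jk} - 1\Bigr]
   & j \in \hat z_i \setminus y_i \quad\text{(extra)}\\[2pt]
 0 & \text{otherwise,}
\end{cases}$$

where $n^* = \max\{n_k : k \in y_i\}$ is recomputed per instance. Predicted
codes that contradict another predicted code ($C_{jk} = 1$) additionally incur
$b_i(j) = -(1/n_j)\sum_{k \in \hat z_i} s_k C_{jk}$. Instance totals
$t_i = \sum_j a_i(j) + b_i(j)$ are summed into $t(Y, Z)$ and normalised
between the inactive system $\Phi$ (empty predictions) and the perfect one:

$$M = \frac{t(Y,Z) - t(Y,\Phi)}{t(Y,Y) - t(Y,\Phi)}.$$

Because truths are validated to be contradiction-free, the two baselines have
the closed forms $t(Y,\Phi) = -\sum_{j:\,n_j>0} s_j$ and
$t(Y,Y) = +\sum_{j:\,n_j>0} s_j$ (each occurrence of code $j$ contributes
$s_j/n_j$, and there are exactly $n_j$ of them); `medtric()` uses the closed
forms and the test suite pins them against a naive double-loop evaluation.

Three consequences worth knowing:

* **Anchors.** An all-empty prediction set scores exactly 0, a perfect one
  exactly 1, for *any* valid configuration.
* **Invariances.** Replicating instances, permuting them, or rescaling all
  $s_j$ by a common factor leaves the score unchanged.
* **Quick heuristics.** On a single instance with $g$ equally significant
  truth codes, missing $d$ of them scores $1 - d/g$ (miss one of three:
  $2/3$); each extra code at constant similarity $w_0$ costs
  $(1 - w_0)/(2g)$.

### Ordering guarantee and its margin

Within an instance, a missed code $j$ costs $s_j/n_j$ while an extra code
costs at most $s_j(1 - \min_k w_{jk})/n^*$, which is strictly smaller whenever
$n_j \le n^*$ — always true for codes in the instance's truth set, since
$n^*$ is the maximum over exactly those codes. At the dataset level,
`clinical_order_margin()` reports, per code,

$$\xi_k = \frac{s_k}{n_k}\Bigl[\mathit{fp}_k\,\frac{n_k}{n^*}(1 - w^*_k)
  - 2\,\mathit{fn}_k\Bigr], \qquad w^*_k = \min_j w_{kj},$$

here with $n^*$ the *dataset-wide* maximum prevalence, the relevant quantity
when comparing a purely-missing against a purely-over-calling system class by
class. All $\xi_k < 0$ certifies that missed diagnoses score below
over-diagnoses. Conservatively this holds whenever each code's false
positives do not exceed twice its false negatives ($n_k = n^*$, any
$w^* > 0$); pushing $w^*_k$ down to $1/3$ extends it to three times, and a
code ten times rarer than the most frequent one tolerates twenty times as
many false positives as false negatives.

## Tunable parameters

| Parameter | Meaning | Default | Why |
|---|---|---|---|
| `significance` $s_j$ | relative clinical importance (unitless) | 1 for all | equal importance unless domain knowledge says otherwise; only ratios matter |
| `similarity` $w_{jk}$ | partial credit for over-calling a condition similar to a true one | constant $w_0 = 0.5$ | neutral midpoint of the admissible $(0,1)$ range when no similarity matrix exists |
| `contradiction` $C_{jk}$ | mutually exclusive pairs | none | contradictions are domain facts, not defaults |
| `prevalence_floor` | substitute for $n_j = 0$ in the contradiction penalty | 1 | keeps the penalty finite and maximal for codes never observed in any truth |

The simulation experiments default to $w_0 = 0.8$ on a 10-code catalog: with
$P = 10$ and $(P - |y|)(1 - w_0) < 2$, the per-instance bucket chain below is
satisfied *deterministically*, so the monotonicity probe isolates failures of
other metrics rather than sampling luck of this one.

## Conventions and edge cases

* **Empty truths are rejected.** The per-instance score averages similarity
  over truth codes and the normalisation maximises over them; both are
  undefined for an empty truth. "No finding" is a real diagnostic outcome and
  must be an explicit catalog code (as normal sinus rhythm is in ECG
  catalogs). Empty *predictions* are valid and describe an inactive system.
* **Mixed predictions** (overlap plus both missed and extra codes) fall
  outside the four-way clinical taxonomy; `classify_prediction()` reports
  them as a fifth kind, and the scoring handles them term by term.
* **Zero denominators** in the baseline metrics (0/0) are defined as 0 —
  this affects classes never predicted and never present, and empty
  predictions.
* **Example-based precision and recall** follow the standard convention:
  precision divides the overlap by the predicted-set size, recall by the
  truth-set size. (Some summaries in the literature print these two swapped.)
* **Score comparisons** in the test suite use an absolute tolerance of 1e-9;
  chain comparisons in the monotonicity probe use 1e-12, with ties counted as
  violations.

## The two stress tests

**Monotonicity probe** (`monotonicity_rate()`). For each of $\rho = 100$
sampled ground truths, $\Gamma = 200$ candidate predictions are drawn from a
synthetic classifier that reports each truth code with probability $p$
(sensitivity) and each other code with probability $1 - q$ (specificity
complement). Candidates of pure type are bucketed by kind and degree; mixed
candidates are discarded (the taxonomy covers only pure types). Each bucket
is scored as the *mean* metric value of its members on one-instance
evaluation sets — the expected score of that error pattern. The sample passes
if the bucket scores strictly increase along

$$\text{wrong}^{t_w} < \dots < \text{wrong}^1 < \text{missed}^{t_m} < \dots
  < \text{missed}^1 < \text{over}^{t_o} < \dots < \text{over}^1 <
  \text{perfect},$$

checked over the buckets present (a sample with fewer than two buckets is
resampled). $\tau$ is the percentage of passing samples; the experiment is
repeated $n = 10$ times under fixed seeds. $\Gamma$ is a package choice
(exposed as `gamma`); 200 candidates populate the common buckets densely at
the default settings. Loss-type metrics (Hamming) are orientation-flipped
before comparison so that larger always means better; the ties and inversions
that make Hamming loss and subset accuracy fail are unaffected by
orientation.

**Dispersion probe** (`dispersion()`). Two classes are mixed in proportion
$\alpha \sim U(0,1)$: each of $l = 100$ single-label truths is the frequent
class $a_M$ with probability $\alpha$, else the rare class $a_m$. Predictions
use per-class sensitivities $p_M = 0.9$, $p_m = 0.5$ and specificity
$q \in \{0.95, 0.99\}$ across the rest of the catalog, holding classifier
quality fixed while only the case mix moves. The dispersion $\sigma$ is the
standard deviation of the metric over $\eta = 50$ draws of $\alpha$; a
prevalence-invariant metric has $\sigma$ near 0. All requested metrics are
evaluated on the *same* simulated draws, so their $\sigma$ values are
directly comparable per repeat.

```{r dispersion-demo}
r <- dispersion(c("medtric", "f1", "accuracy"),
                eta = 20, l = 60, repeats = 3, seed = 11)
sapply(r, function(x) x$estimate)
```

## What the synthetic generator does and does not emulate

`synthesize_dataset()` and the two probes emulate the *label structure* of
multi-label diagnostic data: a finite catalog, truth sets of cardinality 1-3
(typical of diagnostic annotations, where most samples carry one to a few
codes), optional per-class propensity skew, and a classifier fully described
by per-class sensitivity and specificity. They do **not** emulate correlated
label co-occurrence, annotation noise, instance difficulty, or the real
prevalence profiles of clinical datasets. Passing probes therefore certify
properties of the *metrics* under controlled error patterns — they say
nothing about any particular diagnostic model, and dataset-specific
similarity/significance matrices must come from domain experts.

## Problem sizes

The default experiment sizes used throughout the tests and the acceptance
script — $\rho = 100$ truths $\times$ $\Gamma = 200$ candidates $\times$
$n = 10$ repeats for monotonicity; $\eta = 50$ mixes of $l = 100$ instances
$\times$ $n = 10$ repeats per specificity setting for dispersion — are the
package's chosen desk-scale study conditions: large enough that every common
bucket is populated and the Monte-Carlo standard error of $\sigma$ is well
below the gaps being compared, small enough to run in seconds.

## Known limitations

* The ordering guarantee is conditional: with unbalanced prevalence an extra
  prediction of a code *more* prevalent than every truth code can, in
  principle, cost more than missing it; `clinical_order_margin()` makes the
  operative region measurable per dataset.
* The score compares systems on a *fixed* catalog and configuration; scores
  computed under different similarity or significance matrices are not
  comparable.
* Contradiction penalties accumulate per predicted code, so a prediction
  containing $m$ mutually contradictory codes is penalised $m$ times — by
  design disqualifying, but worth knowing when $C$ is dense.
* Bucket scores in the monotonicity probe use the mean over members; other
  reductions (median, worst-case) would probe slightly different properties.
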