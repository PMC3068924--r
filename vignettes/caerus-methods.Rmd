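---
title: "Domain-interaction network signatures: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Domain-interaction network signatures: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caerus)
```

## The problem

Gene-expression signatures picked purely for their univariate association
with cancer outcome generalize poorly across cohorts. A more robust idea is
to anchor the signature in the *structure* of the protein interaction
network: proteins whose interactions all pass through a single physical
interface ("singlish-interface" hubs) are points where a mutation or an
expression change can disrupt many interactions at once, because partners
binding the same interface are mutually exclusive. caerus scores each
protein by how concentrated its interaction interfaces are, selects
high-scoring proteins as gene signatures, and classifies patient outcome
from how strongly each patient's expression profile decouples those
signatures from their network neighbors.

## The domain index score

The interactome bundle combines a PPI graph, a protein-to-domain
annotation, a catalog of structurally observed domain-domain interactions
(DDIs), and per-domain somatic mutation counts.

For a protein $x$ with domains $D(x)$, each domain $d$ gets an engagement
count $\mathrm{NumDDIs}(d)$: the number of (neighbor, neighbor-domain)
*instances* $(p, d')$ with $p$ a PPI neighbor of $x$, $d'$ annotated on
$p$, and $(d, d')$ in the DDI catalog. Counting instances rather than
distinct DDI types is deliberate: a singlish hub realizes one DDI type
with many partners, and the instance count is exactly what makes it stand
out. (The distinct-type reading is available via
`score_config(count_distinct = TRUE)` for comparison.)

The plain score exponentially rewards heavily engaged domains:

$$S(x) \;=\; \sum_{d \in D(x),\; \mathrm{NumDDIs}(d) \ge 1} 2^{\mathrm{NumDDIs}(d)}.$$

Domains with zero realized DDIs contribute nothing (not $2^0 = 1$):
otherwise domain-rich but non-interacting proteins would accumulate score
from annotation alone. The base 2 is a tunable `weight_base`; anything
$> 1$ preserves the ranking logic.

With somatic mutation counts $\mathrm{NumSMs}(d)$, the mutation-weighted
score multiplies each engaged domain's term by $1 + \mathrm{NumSMs}(d)$
(default `mutation_mode = "multiplicative"`); an additive variant
($S + \sum_d \mathrm{NumSMs}(d)$ over engaged domains) is provided as a
config alternative. The multiplicative form was chosen as the default
because it inflates precisely those scores where mutations hit
heavily-engaged interfaces — consistent with the observation that the
tuned selection threshold rises (50 → 80) once mutations are folded in —
and because it guarantees the mutation-weighted score never falls below
the plain one for non-negative counts, which both variants satisfy and the
tests assert.

A protein is a **gene signature** when its chosen score is strictly
greater than the threshold $c$ ("over the threshold" read as strict;
`score_config(strict = FALSE)` switches to $\ge$).

`classify_interface()` labels a protein *singlish* when exactly one DDI
type is realized with at least two distinct neighbors, *multiple* when two
or more types are realized, and *none* otherwise. A single DDI type
realized with a single neighbor is classed *none*: with one partner there
is no mutual exclusivity to speak of, which is the phenomenon the class is
meant to capture.

`domain_overrepresentation()` compares, for each domain of the signature
set, its share of realized DDI instances within signatures against its
genome-wide share, with a one-proportion Z-test (normal approximation,
two-sided). The test form is a design choice; when the signature share
equals the null share exactly the statistic is defined as $z = 0$,
$p = 1$, so "signatures = everything" degenerates cleanly.

## From expression to features

Two related quantities are computed over the PPI neighborhood
$P = \{p_1, \dots, p_n\}$ of a signature $x$:

**Group-level discrimination score** (a training-set diagnostic):
$$\mathrm{DS}(x) \;=\; \frac{1}{2n} \sum_{i=1}^{n}
  \left| r_{x,p_i,\mathrm{good}} - r_{x,p_i,\mathrm{poor}} \right|,$$
with $r$ the Pearson correlation of $x$ and $p_i$ across the patients of
one outcome group. The factor $1/2$ maps the raw range $[0, 2]$ onto
$[0, 1]$, making the declared unit range exact. Neighbors missing from
the expression matrix, or with an undefined (constant-vector)
correlation, are dropped and $n$ reduced; no imputation is attempted.

**Per-patient feature** (what the classifier consumes): the group-level
Pearson form cannot produce one value per patient, yet the classifier
needs exactly that. The feature adopted is the per-patient mean absolute
expression difference between signature and neighbors on a rank-scaled
profile:
$$v_x(\text{patient}) \;=\; \frac{1}{|N_x|} \sum_{p \in N_x}
  \left| \hat e(x) - \hat e(p) \right|,$$
where $\hat e$ is the patient's expression column ranked ascending
(average ranks on ties) and mapped to $(\mathrm{rank}-1)/(G-1) \in
[0, 1]$. Rank scaling guarantees the $[0, 1]$ range the 20-bin
discretization requires, regardless of platform, and makes features
invariant under any strictly monotone per-patient transformation of the
raw values. A raw min–max mode (`mode = "raw"`) is kept behind a flag for
comparison. In a good-outcome patient a tightly coupled signature and its
partners sit at similar ranks (small $v$); decoupling pushes $v$ up.

## The classifier

Features are discretized into 20 half-open bins $[k/20, (k+1)/20)$, with
1.0 folded into bin 19. The naive Bayes model estimates class priors as
empirical frequencies $X_\mathrm{good}/X$ and per-signature bin
likelihoods as $(\text{count} + \alpha)/(X_c + 20\alpha)$. The Laplace
pseudocount $\alpha = 1$ is the default: with ~20 bins and small classes,
empty bins are the rule, and an unsmoothed model assigns zero posterior
the moment a test patient lands in a bin unseen during training.
$\alpha = 0$ reproduces the plain empirical estimator. Prediction is MAP
over $\log P(C) + \sum_s \log P(v_s \mid C)$, computed in log space with
log-sum-exp normalization (products of 20-bin probabilities over a
hundred signatures underflow double precision). Exact ties go to "good",
the majority outcome in the cohorts this method targets, which is the
conservative direction for poor-outcome calls.

## Evaluation protocol

The positive class is "poor". Accuracy, sensitivity and specificity
follow the usual confusion-matrix formulas; a ratio with an empty
denominator is reported as `NA` rather than 0. ROC curves sweep the
unique posterior values (tied scores cross the threshold together) and
the AUC is the trapezoidal area.

`nested_cv()` implements the threshold-tuning protocol: 5 stratified
outer folds from a seeded shuffle; within each 80% training portion every
candidate $c$ is scored by leave-one-out CV (fit on the remaining
training patients, predict the held-out one), the $c$ maximizing LOOCV
accuracy wins, ties going to the smallest $c$ (larger signature sets —
raising $c$ shrinks the set and empirically degrades performance). The
winning $c$ trains on the full 80% and predicts the 20%. Stratification
is a deviation from a plain shuffle, adopted because outcome classes are
typically imbalanced (~30% poor) and unstratified folds occasionally
lose a class entirely. Signature selection uses only the interactome —
it is label-free — so it sits safely outside the fold loop; the
per-patient features likewise depend only on each patient's own column.
Only the naive Bayes fit and the choice of $c$ see training labels, and
they see training patients only. `loocv()` is the small-cohort variant:
outer leave-one-out with the same inner tuning on each $n-1$ subset.
Headline metrics are pooled over out-of-fold predictions (per-fold values
are reported alongside); pooling was chosen over per-fold averaging
because LOOCV folds of size 1 have no meaningful per-fold metric.

## The simulator

`simulate_bundle()` builds the structure the scoring model assumes, with
known ground truth. Each of the `n_singlish_hubs` planted hubs receives a
dedicated hub domain and a dedicated partner domain; its `hub_degree`
partners carry the partner domain and only the (hub, partner) pair enters
the catalog for them. Consequently the hub's engagement count is exactly
`hub_degree` through one interface: interface class singlish, plain score
$2^{\texttt{hub\_degree}}$ by construction (256 with the default degree
8, comfortably above the canonical threshold 50). The background is an
Erdős–Rényi graph (edge probability 0.01 over 200 proteins, mean degree
~2) with Poisson-distributed annotation (mean 2 domains per protein) from
a disjoint domain pool and a sparse background DDI catalog (density
0.005), so background proteins score far below 50 with high probability.
Hub domains draw Poisson(2) somatic mutation counts; background domains
none.

`simulate_cohort()` plants the class-dependent co-expression the method
detects: per patient, each hub's expression is a standard normal signal;
partner expression is `signal + N(0, noise_sigma)` for good-outcome
patients and `(1 - effect_delta) * signal + N(0, noise_sigma)` for poor,
so `effect_delta` attenuates hub–partner coupling in the poor class and
`effect_delta = 0` defines an exchangeable null cohort. Default cohort
sizes are 60 good / 40 poor with `noise_sigma = 0.2`. Gaussian noise with
linear coupling is the simplest generative model producing the
correlation structure the method assumes; it does not attempt real
microarray marginals, platform or batch effects, probe redundancy, or
scale-free PPI degree distributions. Passing tests on simulated data
therefore demonstrate correctness of the machinery and recoverability of
a planted signal — not clinical performance on real cohorts, which
depends on database versions and cohort composition outside this
package's scope.

All generation is seeded and restores the caller's RNG state; the cohort
stream is offset from the bundle stream so the two draws are
independently reproducible.

## Numerical and degenerate-input choices

* Duplicate PPI records and self-interactions are dropped on input with a
  logged count; proteins present only in the annotation are retained as
  isolated nodes; unannotated proteins score 0.
* Identifiers are opaque, case-sensitive strings; no gene-symbol or
  accession mapping is attempted.
* A constant expression vector makes a Pearson correlation undefined; the
  neighbor is excluded with a warning and the denominator reduced.
* An all-tied rank-scaled column maps to 0.5 everywhere.
* Feature values outside $[0, 1]$ (possible only through user-supplied
  matrices) are clamped with a warning before binning.
* With $\alpha = 0$ a zero-likelihood bin sends a class score to
  $-\infty$; if both classes are impossible the patient is called "good"
  with a warning and posterior 0.5.
* Problem sizes in the test-suite protocols (200-protein bundles,
  100-patient cohorts, 20-seed recovery sweeps) were chosen as the
  smallest at which the planted-signal and null properties are stable;
  they run in seconds.

## Known limitations

* The per-patient feature is a reconstruction choice: the group-level
  Pearson definition and the per-patient consumption cannot both be taken
  literally, so the package exposes both (diagnostic vs feature) rather
  than guessing a single intent.
* The enrichment Z-test uses a normal approximation; for tiny instance
  counts an exact binomial test would be preferable.
* Somatic mutation counts are aggregate per domain, not per patient;
  patient-specific mutation weighting is out of scope.
* No survival-time modeling: outcomes are the two labels only.
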