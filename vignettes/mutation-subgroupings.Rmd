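---
title: "Detecting divergent transcriptomic signatures within a cancer gene's mutations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting divergent transcriptomic signatures within a cancer gene's mutations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutsubsig)
library(dplyr)
```

## The problem

Tumour cohorts routinely come with two matched data types: somatic point
mutation calls and bulk expression profiles. For many cancer genes, the
presence of *any* point mutation leaves a detectable downstream imprint on
the transcriptome, so a classifier trained to predict mutation status from
expression achieves an AUC well above chance. But a gene's mutations are
not interchangeable: a frameshift truncating a DNA-binding domain, a
hotspot missense in a kinase domain, and a silent substitution can have
entirely different regulatory consequences. Treating all of them as one
"mutated" class can dilute — or completely mask — the signature of the
subset that actually drives expression changes.

`mutsubsig` operationalises this idea. It enumerates *subgroupings* of a
gene's point-mutated samples by organising variants into property
hierarchies, trains an expression-based classifier for every subgrouping
under one fixed cross-validation protocol, and then asks, statistically,
whether any subgrouping's signature *diverges* from the gene-wide one.

## Mutation trees and subgrouping enumeration

Variants are organised along four fixed ordered property hierarchies
(`hierarchy_specs()`):

1. exon → codon location → amino-acid substitution,
2. consequence → exon,
3. SMART domain → consequence,
4. Pfam domain → consequence.

Each hierarchy yields one tree per gene; every node (leaf or internal) is
a candidate branch carrying the set of samples with a matching variant.
The unassigned value `"."` is a first-class branch value — splice variants
without an exon assignment form their own branch, which matters in
practice because such branches can carry strong signatures.

A subgrouping is a single branch with at least 20 mutated samples, or a
union of two non-nested branches with at least 10 samples each (optionally
three branches with at least 5 each and 20 in total, in the expanded
search). Subgroupings equal to the gene-wide mutant set are discarded as
equivalent to the gene-wide task, and identical sample sets arising from
different hierarchies are flagged as aliases so each distinct set is
evaluated once.

Two enumeration details are our own choices where the rules above leave
room. First, a pair's union must reach twice the per-branch minimum
(20 samples at the defaults): branches can overlap through samples
carrying several variants, and this keeps the guarantee that every
emitted subgrouping has enough positive examples to train on. Second,
when one sample set has several descriptions, the canonical one is the
shallowest (fewest branches, then fewest hierarchy levels), which favours
`exon=1` over `consequence=missense,exon=1`.

Beyond the trees, subgroupings can be formed by adding deep copy-number
alterations (discretised calls ±2) to a point-mutation subgrouping when
at least 5 novel carriers exist (`augment_with_cnas()`), and by sweeping
observed PolyPhen (damaging direction, ≥) or SIFT (≤) scores for
thresholds that produce distinct sets of at least 20 samples
(`threshold_subgroupings()`); the latter are totally ordered by inclusion
by construction.

```{r enumerate}
fx <- pik3ca_fixture()
tree <- build_mutation_tree(fx$variants, "exon_location_substitution")
filter(tree, level == 1)
catalogue <- enumerate_subgroupings(tree)
nrow(catalogue)
```

## Classification protocol

Expression is prepared once per cohort (`prepare_cohort()`): only
protein-coding features on autosomes are kept, features with missing
values are dropped, the bottom decile by mean raw value is removed, and
the rest is `log2(x+1)`-transformed and z-scored per feature. The log
base and pseudocount are not dictated by anything upstream; `log2(x+1)`
is the convention for RSEM-style quantifications, and any monotone log is
equivalent up to the z-scoring scale. Z-scoring is fit on the full cohort
by default, reproducing the preparation-before-splitting order of the
protocol; note this leaks marginal feature statistics across folds — the
labels, which are what the AUCs measure, are never leaked. Constant
features are dropped (with a warning) rather than producing divide-by-zero
z-scores. For every task, all features on the task gene's chromosome are
excluded (`task_feature_mask()`), so a classifier cannot read the mutation
off cis effects or the gene's own transcript.

Each subgrouping becomes a binary task over the whole cohort: members of
the subgrouping's sample set are positive, everyone else — including other
mutants of the same gene — is negative. The classifier protocol is fixed:

* ten iterations of fourfold cross-validation, with the same forty
  train/test splits shared by every task on a cohort
  (`make_cv_splits()`), so per-iteration AUCs are comparable across
  tasks;
* per training sub-cohort, the hyperparameter is tuned by the
  *worst-of-four* rule (`tune_fold()`): each grid value is fit on four
  random 80% subsets and scored on the complementary 20%s, its merit
  being the minimum of the four AUCs; the argmax-of-minimum wins;
* the tuned model is refit on the full training sub-cohort and emits
  continuous positive-class confidences for the held-out quarter, so all
  scores are out-of-fold and every sample collects exactly one score per
  iteration (forty fitted models per task, `fit_predict()`).

The default classifier is ridge-penalised logistic regression (glmnet
behind the scenes, with the scikit-learn-style C grid mapped through
`lambda = 1/(nC)`; one path fit covers the whole grid). RBF-SVM, random
forest and a deeper ridge grid are available; all use balanced class
weights. Two numerical choices: the glmnet convergence threshold is
relaxed to `1e-5` (the tuning merit is an AUC over a held-out fifth of a
training sub-cohort — rank changes below this tolerance are far smaller
than the merit's sampling noise), and merit ties break toward the more
regularised value, which is deterministic and conservative. Forests use
500 trees by default (configurable) rather than thousands, as tree count
affects variance, not the protocol.

A property of this protocol worth knowing: because the tuned
regularisation strength can differ across the four folds of an iteration,
and pooled fold scores are probabilities on different calibration scales,
the pooled per-iteration AUC (and the task AUC from mean scores) sits
noticeably below the within-fold AUC when the tuning merit is noisy —
with few positives, the worst-of-four merit barely separates grid values.
This is inherent to pooling fold predictions under per-fold tuning; we
keep it because the whole downstream statistical machinery
(cv-significance, DeLong divergence) is defined on exactly these pooled
scores, and all tasks on a cohort share the same splits, so comparisons
remain like-for-like.

## Divergence statistics

For each task, the *task AUC* is the pairwise probability that a random
mutant's mean score (across the ten iterations) exceeds a random
wild-type's, ties counting one half — exactly the Mann–Whitney identity
`U/(n1 n0)`, which is also how `pairwise_auc()` computes it. Each
iteration additionally yields a *cv-AUC* from its own scores.

Three complementary statistics probe divergence of a subgrouping task S
from its gene-wide task G:

* **cv-significance**: S beats G on *all ten* iteration-aligned cv-AUC
  comparisons, strictly. Under exchangeability a sweep in a fixed
  direction has probability at most 2^-10 per ordered pair; the strict
  inequality means a single tie fails the sweep.
* **DeLong divergence** (`delong_divergence()`): both classifiers' mean
  scores are evaluated against S's labels, and a one-tailed paired DeLong
  test (placement-value covariance estimator) asks whether S's scores
  discriminate S's own labels better than G's scores do. A significant p
  says the subgrouping classifier found a genuinely different way of
  separating its samples, not merely a cleaner subset of G's positives.
  Zero-variance differences are degenerate: identical score vectors give
  the neutral p = 0.5, anything else (e.g. both AUCs exactly 1) returns a
  conservative p = 1 with a flag. p values are reported raw — the
  protocol's stringency comes from the all-ten rule and the matched
  nulls, not from multiplicity adjustment — though a Benjamini–Hochberg
  column is one `p.adjust()` call away.
* **matched random nulls** (`random_backgrounds()`, `null_comparison()`):
  for each subgrouping, five tasks with positives drawn uniformly from
  the cohort and five drawn from the gene's mutants, all size-matched.
  The subgrouping's AUC percentile within its backgrounds, and
  cv-significance against the best background, separate "the hierarchy
  found something" from "any random subset of this size does as well".
  Gene-specific draws are unconstrained — they may occasionally resemble
  the subgrouping itself, which only makes the null conservative.

Fitted ridge tasks can also be *transferred*: the forty models are applied
to another prepared cohort (features intersected, the chromosome mask
re-applied), each sample getting the mean of forty outputs
(`transfer_scores()`, `transfer_auc()`). By default the target is
evaluated on its own z-score scale — its "processed expression" — with an
option to re-standardise the target's log values using the training
cohort's scaling parameters instead, for the reading that treats the
scaler as part of the trained model. Mean coefficient vectors across
the forty folds summarise what each classifier reads
(`coefficient_summary()`): tasks above an AUC floor of 0.7 are clustered
by average-linkage agglomeration on `1 - Spearman` distances into five
groups (average linkage is the standard companion of correlation
distances; the cut count follows the reporting convention), with a
display filter hiding tasks dominated by a same-cluster task of higher
AUC and sample-set Jaccard ≥ 0.9. Transferred scores can finally be
correlated with cell-line drug response (`drug_response_correlation()`):
per drug measured in at least 100 scored lines, the Spearman rho between
AUC50 and mean prediction, reported both raw and negated (the negated
convention makes larger values mean stronger association with
sensitivity).

## The synthetic cohort generator

Nothing in the statistical machinery can be validated on real cohorts
inside a test suite, so the generator (`generate_cohort()`) produces
cohorts with known ground truth: a standard-normal expression background
in which each planted mutation branch adds `delta * v` to its member
samples, `v` a unit effect vector on a dedicated feature block. Distinct
programs occupy disjoint blocks and are therefore exactly orthogonal;
sharing a program id shares the direction. Planted genes sit on reserved
chromosomes away from program features, so the per-task chromosome mask
never removes planted signal. The matching variant table uses the same
dialect the readers consume, and the truth record pins memberships,
effect vectors and sizes.

This is deliberately the minimal generative model under which a linear
classifier is well specified — an additive linear program plus Gaussian
noise. It emulates the *statistical* structure the pipeline assumes
(mutation-linked expression programs over a background), not RNA-seq
count noise, batch structure, tumour purity, or correlated co-expression
modules. Passing tests therefore demonstrate that the machinery recovers
planted structure under its own assumptions; they do not certify
performance on real cohorts. Matrices come out on the prepared (z-like)
scale directly; `prepare_cohort()` is exercised separately on raw
non-negative matrices.

`generate_scenarios()` fixes five qualitative regimes — homogeneous,
active/inactive, orthogonal, graded, null — at 500 samples x 1000
features with 100 planted mutants (20%), mirroring a mid-sized tumour
cohort. The planted effect size 4.5 was calibrated once so that a
50-mutant active subgrouping reaches a task AUC near 0.9 under the full
pipeline, and then frozen. The calibration absorbs the pooled-score
attenuation discussed above, which is why it exceeds the ideal-observer
effect size (`qnorm` arithmetic would suggest ~1.8 for a Bayes AUC of
0.9); the recovery and orthogonality tests reproduce the resulting AUCs.

```{r scenario, eval = FALSE}
scen <- generate_scenarios(seed = 1)
sim <- generate_cohort(scen$active_inactive)
scheme <- make_cv_splits(sim$cohort, seed = 1)
gw <- gene_wide_task(sim$variants, sim$cohort)
res <- fit_predict(gw, sim$cohort, scheme, seed = 1)
glance(res)
```

## Orchestration

`run_enumerate()`, `run_experiment()` and `report_divergence()` tie the
stages together: enumeration over all four hierarchies with alias
deduplication, then gene-wide, subgrouping and background tasks under the
shared splits, then a per-gene table of the best subgrouping with its
cv-significance flag, DeLong p and null percentile. Results directories
are resumable at task granularity — completed score matrices are reloaded,
and a directory written under a different configuration hash refuses to
resume. All randomness derives from the single experiment seed through
stable string hashes of task descriptors, so growing a catalogue never
perturbs existing draws. A thin command-line wrapper over these functions
ships in `inst/scripts/mutsubsig`.

## Problem sizes, defaults, and limitations

The package's own test and validation runs use deliberately modest sizes —
cohorts of 150–500 samples and 300–2000 features, ten to fifty simulation
replicates — chosen so that the full protocol (forty fits per task, eight
grid values, four tuning subsets) runs comfortably on a desktop while
leaving the protocol constants untouched.

Known limitations, beyond the generator's idealisations listed above:

* cv-significance is a fixed-stringency rule, not a calibrated test; its
  false-positive rate under dependence between tasks is bounded only
  empirically (the homogeneous scenario).
* The worst-of-four merit is noisy for tasks with few positives, which
  both widens the spread of chosen regularisation strengths and
  attenuates pooled AUCs (see above); results for subgroupings near the
  20-sample floor should be read with that in mind.
* Transfer assumes the target cohort's prepared feature space overlaps
  the training one substantially; coefficients of missing features are
  dropped, which degrades gracefully but silently.
* The down-weighting of nonlinear kinds is a scope choice: the linear
  generative model gives linear classifiers home advantage, and no claim
  is made about nonlinear signal in real data.
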