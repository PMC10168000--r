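---
title: "Classifying database identifiers: model, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying database identifiers: model, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Biological databases assign their own accession strings to entities, and the
same gene, transcript, protein or compound carries a different identifier in
every database describing it. `idsleuth` treats "which database minted this
string?" as a supervised multi-class classification problem over the
string's surface form.

The representation is deliberately primitive: an identifier of at most $L$
characters becomes a length-$L$ integer vector whose $j$-th entry codes the
character at position $j$ (pad code 0 past the end). This works because
accession grammars are strongly positional — literal prefixes, fixed-width
digit runs, punctuation at fixed offsets — so class information concentrates
in the early positions, and padding concentrates non-information in the
trailing ones. The model assumes identifiers are short (tens of characters),
case-sensitive, and drawn from a fixed character inventory; it does not see
n-grams, lengths as explicit features, or any semantics.

Four learners are trained on the encoded matrix — a single decision tree
(CART via rpart), a random forest (ranger), gradient boosting (xgboost) and
a small dense neural network — and combined by voting. The redundancy is the
point: the members fail differently, and the unification rule exploits their
held-out error profiles.

## Stages and their parameters

**Cleaning** drops rows with empty/missing identifiers and exact duplicate
`(id, class)` pairs; it is idempotent.

**Encoding** uses a fixed map: digits `0`–`9` → 1–10, `A`–`Z` → 11–36,
`a`–`z` → 37–62, then `. _ - : / ( )` → 63–69; pad = 0. The inventory and
the map are stored with a trained model, so prediction always uses the
training map. Case matters (`ENSG…` vs `uc…`), hence no folding. Two
prediction-time degeneracies are handled leniently rather than fatally:
identifiers longer than the training pad length are truncated with a
warning, and characters outside the training inventory map to the pad code
with a warning. At training time the same situations are errors, since they
indicate a malformed corpus.

**Splitting and balancing.** Per class of size $n$, the training side gets
$\mathrm{round}(0.7\,n)$ uniformly sampled rows (R's `round()`, half-to-even
at exact midpoints) and the test side the remainder. The rounding direction
is not cosmetic: it is the unique convention under which the closed-form
balanced training count
$\mathrm{round}(0.7n) + \max(0, T - n)$, with per-class target
$T = \lceil \text{mean class size} \rceil$, reproduces the reference
corpus's published per-class balanced counts on all 39 classes — the
acceptance suite checks every row. Minority classes are raised to $T$ with
SMOTE: each synthetic row interpolates a real training row toward one of its
$k = 5$ nearest same-class neighbours (Euclidean distance on the codes) with
a uniform weight, then every coordinate is rounded to the nearest integer so
synthetic rows stay on the code grid. $k$ shrinks to $n-1$ for classes
smaller than $k+1$; a single-row class is duplicated with a warning. Test
partitions never contain synthetic rows. Random undersampling of majority
classes is available (`undersample = TRUE`, cap ratio configurable) but off
by default: the reference corpus's majority-class counts equal plain 70%
splits, i.e. the published balanced counts show no undersampling, so the
default follows the arithmetic rather than the prose describing it.

**Feature filtering** combines two screens with documented defaults, since
no numeric thresholds were published: (i) drop positions whose
Gini-impurity-decrease importance (from a seeded 100-tree forest) is below
1% of the maximum; (ii) among survivors, walk in decreasing importance and
drop any position correlated above $|r| = 0.95$ with an already-kept one.
Integer codes are treated as numeric for Pearson correlation — they are
ordinal at best, which is acceptable for a redundancy heuristic but would
not support inference. Constant (all-pad) columns have undefined
correlation; they are assigned 0 off-diagonal so that padding columns are
judged by importance alone, where they score exactly 0. The top-importance
feature always survives, so the filter can never empty the feature set.

**Learners.** Default hyperparameters are tuned operating points: CART
(complexity 0.00053, max depth 24, min node 4), random forest (385 trees,
max depth 368, Gini splits, minprop 0.017, impurity importance), XGBoost
(eta 0.29, max depth 8, subsample 0.84, gbtree, $\gamma = 0$,
$\lambda = 0.92$, 10 rounds, column sampling 0.99, $\alpha = 0.014$), and
the network (two hidden layers of 40 ReLU units, softmax output, Adam at
its standard rates, categorical cross-entropy, 64 epochs, batch 128). The
network's architecture follows the usual fixed-modest-hidden-size rule of
thumb; input width is the number of kept positions and output width the
number of classes. No installed R package provides this architecture, so
the package implements the network directly in matrix algebra (He-uniform
initialisation, minibatch Adam); at these sizes the cost is dominated by
BLAS-level matrix products. All backends run single-threaded so a seed
fully determines a fit.

**Hyperband tuning** (optional, `tune = TRUE`) races uniformly sampled
configurations: with halving factor $\eta = 3$ and four stages, bracket
$s = 3\ldots0$ starts $\lceil 4/(s+1)\cdot 3^s \rceil$ configurations —
27, 12, 6, 4, i.e. 49 in total — and after each stage the lowest-loss third
advances to a threefold larger budget. Two quantities were left open by the
published description and are fixed here as documented choices: the
resource unit is the *fraction of training rows* used for the fit
(stratified so every class stays represented), and the tuning loss is the
classification error on a fixed seeded 80/20 holdout of the training
partition. Ties in survivor selection and in the final argmin break by
sampling order. Search spaces are bounded boxes around the default
operating points (see `learner_space()`).

**Ensemble unification.** A label voted by at least three of the four
models wins directly. Anything else — 2-2 or 2-1-1 — counts as scattered
and goes to scoring: model $N$ voting class $x$ scores
$$ N_\text{score} = F1^N_x \prod_{R \neq N,\; y = \mathrm{val}(R)}
   \bigl( c + (1-c)\, P(y \mid x)^R \bigr), $$
and the highest-scoring model's vote wins. $P(y\mid x)^R$ is read as the
row-normalized held-out confusion probability that a sample truly of class
$x$ is predicted $y$ by $R$; the published prose is directionally
ambiguous, and this direction is the one under which a disagreeing peer
that often confuses $x$ with its own vote fails to discount $N$'s score —
the behaviour the scoring rule is meant to produce. The influence constant
$c$ defaults to 0.5 (no published value; 0.5 weights peer evidence and
per-class F1 evenly, and both extremes are degenerate: $c=1$ ignores peers
entirely, $c=0$ vetoes any vote a peer never reproduces). The score is
affine and non-decreasing in each $P(y\mid x)^R$ with slope
$F1^N_x (1-c) \prod_{\text{others}} (\cdot)$; the published sensitivity
statement $\partial/\partial P = 1 - c$ is the same fact with the constant
factors suppressed, and is treated as qualitative, not as an identity to
implement. Score ties break by macro-F1, then by fixed model order (rf,
xgb, mlp, cart), so predictions are deterministic. Classes absent from a
model's test partition get uniform misclassification rows with a warning —
a flagged evaluation-coverage gap, not silent behaviour.

**Metrics.** Per class, one-vs-rest reductions give TP/FP/TN/FN with
$Acc = (TP+TN)/\text{total}$, $Pre = TP/(TP+FP)$, $Rec = TP/(TP+FN)$,
$F1 = 2TP/(2TP+FN+FP)$. The published formula sheet swaps FN and FP in
precision and recall relative to their universal definitions; the
implementation uses the standard definitions and records the discrepancy
here. $0/0$ cells are reported as 0 with an `undefined` flag so tables stay
rectangular.

## What the synthetic registry emulates — and what it does not

The built-in registry holds 39 classes named after common databases with
*emulated* templates: literal prefixes plus digit/letter/hexadecimal runs
mimicking each database's accession shape (`ENSG` + 11 digits,
`CHEMBL\d+`, `HGNC:\d+`, ...). They are not authoritative identifiers.org
patterns. Two deliberate departures from realism matter for interpreting
results:

* The classes are constructed to be (near-)separable from positional codes
  alone — distinct prefixes, disjoint accession letter ranges, letter-case
  contrasts. Real corpora are not: gene-name-style classes (WikiGene,
  UniProt gene symbols) genuinely overlap in surface form, and broad
  patterns swallow narrow ones. Tests passing on this registry therefore
  validate the *pipeline machinery* — encoding, balancing arithmetic,
  filtering, training, unification — not classification difficulty on real
  identifier corpora, where minority-class precision is known to suffer.
* Generated identifiers are unique within a class but sampled uniformly
  over the template's space, whereas real accessions are assigned densely
  from the low end of their ranges and carry version suffixes,
  deprecations and historical quirks.

The companion `reference_profile()` carries the per-class sizes of the
corpus the method was developed on (2,751,478 identifiers, 39 classes,
imbalance about 14,702:1 reducing to about 12:1 after balancing); it drives
the closed-form balancing checks and full-scale emulation.

## Problem sizes and numerical choices

The test suite and the acceptance script run the full pipeline on the
39-class registry at 1,000 identifiers per class (39,000 rows, 27,300
training after the 70/30 split; no SMOTE is triggered because the classes
are equal), with the network at 10 epochs — enough for the ensemble while
keeping a test run in tens of seconds on one core. The network's own
accuracy criterion uses its default 64 epochs. Smaller fixtures (2–6
classes, 40–60 identifiers each) exercise every stage in seconds.
Determinism is end-to-end: one master seed fans out to per-stage seeds by
hashing the stage label (`stage_seed()`), so any stage can be re-run in
isolation with the randomness it saw inside the full run, and two runs with
identical config and seed produce byte-identical outputs.

## Known limitations

* Truncation at the training pad length discards information in
  prediction-time identifiers longer than anything seen in training.
* SMOTE interpolation treats positions as ordinal quantities; rounding
  keeps rows on the code grid but interpolated codes need not form a valid
  identifier of the class. That is acceptable for decision-boundary
  support, not for generating plausible accessions.
* The misclassification direction of $P(y|x)$ and the constant $c$ are
  configurable precisely because the published description pins down
  neither; conclusions sensitive to either should be checked at alternative
  settings.
* Pattern matching (`match_patterns()`) is a prefilter, not a classifier:
  overlapping templates legitimately return multiple classes.
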