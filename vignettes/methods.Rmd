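---
title: "Methods: combining similarity transfer and convolutional sequence models for GO prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: combining similarity transfer and convolutional sequence models for GO prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protgo)
```

## The problem

Given a protein's amino-acid sequence, predict the set of Gene Ontology
(GO) classes that describe its molecular functions, biological processes
and cellular components. GO is a directed acyclic graph over three
namespaces, and annotations obey the *true path rule*: a protein
annotated with a class implicitly carries every ancestor of that class.
Predictions therefore have to be hierarchy-consistent sets, not
independent labels, and evaluation has to be protein-centric rather than
per-label.

`protgo` implements a two-component predictor plus the surrounding
machinery: ontology handling, evidence filtering, information content,
consistency post-processing, CAFA-style evaluation, and a synthetic
benchmark generator so that every stage can be exercised offline.

## The two scoring components

**Similarity transfer.** For a query $q$ with a set $E$ of similar
database sequences (a BLAST/DIAMOND tabular hit list filtered at e-value
$\le 10^{-3}$), the score of class $f$ is the bitscore-weighted vote

$$S_{\mathrm{sim}}(q,f) \;=\;
\frac{\sum_{s \in E} \mathbf{1}\!\left[f \in T_s\right]\,\mathrm{bitscore}(q,s)}
     {\sum_{s \in E} \mathrm{bitscore}(q,s)},$$

where $T_s$ is the propagated annotation set of subject $s$. Scores lie
in $(0,1]$; because $T_s$ is closed upward, parent scores dominate child
scores by construction. Multiple HSPs for one (query, subject) pair are
collapsed to the maximum bitscore — the vote needs one weight per
subject, and the maximum-scoring alignment is the natural summary.
During evaluation, self-hits are excluded so that a query present in the
annotation corpus cannot vote for itself.

**Convolutional classifier.** The sequence model is a multi-kernel 1D
CNN over one-hot encoded sequences (21 symbols: 20 residues plus an
"unknown" bucket; 2000 positions at production scale, truncating longer
sequences). One convolutional layer per kernel size (defaults
$\{8, 16, \ldots, 128\}$, 512 filters each) is followed by global max
pooling — the pooled value indicates whether a filter matched anywhere
along the sequence — and the concatenated pooled vector feeds a single
fully connected sigmoid layer, one unit per vocabulary class. The
vocabulary is the set of classes annotated to at least `min_count`
proteins (50 at production scale; smaller for desk-scale corpora), with
namespace roots excluded since they are trivially true for every
annotated protein and carry no discriminative signal.

Several architectural details are deliberate choices where the design
was open. The convolutions are linear and the nonlinearity is the max
pool itself (ReLU is selectable); with one-hot inputs a linear filter is
already a position-weight-matrix matcher, which is exactly the
motif-detection role the pooled "filter active" signal plays. Training
minimises per-class binary cross-entropy with Adam, a seeded validation
split, and early stopping on validation loss, keeping the
best-validation-epoch parameters; the output bias is initialised at the
label prior log-odds, which substantially speeds convergence on sparse
multi-label targets. All of it is deterministic given the config seed.
The convolution forward/backward passes are implemented in C++; because
the input is one-hot, a convolution reduces to a gather-and-sum over
residue indices and never materialises the encoded tensor.

**Ensemble.** The final score is the weighted sum
$S = \alpha\, S_{\mathrm{sim}} + (1-\alpha)\, S_{\mathrm{cnn}}$ over the
union of supports, a missing component contributing 0. We default to
$\alpha = 0.5$ — the weight is defined but no deployed value is
canonical, and at equal weight neither component is privileged;
`--alpha` overrides it globally. $\alpha = 1$ and $\alpha = 0$ reproduce
the pure similarity and pure CNN predictors exactly, which the tests
assert as identities.

## Consistency and output

Raw ensemble scores need not respect the hierarchy, so a post-processing
pass sets each class's score to the maximum over itself and all its
subclasses, walking the DAG in reverse topological order. The result is
monotone along every edge (the namespace root carries the block
maximum), idempotent, and never decreases a score. Thresholding then
keeps classes with score $\ge t$, default $t = 0.3$, the Fmax-optimal
operating point at production scale. We use the closed (minimum
confidence) comparison because it matches the thresholding semantics
users expect from a confidence cutoff; a strict variant is a switch.
One convention matters for dense representations: a score of exactly 0
means "unscored" and never counts as a prediction, so zero-filled dense
matrices and sparse score maps give identical results at $t = 0$.

Formatted output groups predictions by namespace, sorts by descending
score with lexicographic tie-breaks, and attaches the similarity
provenance hits sorted by bitscore; JSON and TSV serialisations are
provided. Classes scored by a model but absent from the loaded ontology
release (version skew) are dropped with a warning before consistency
enforcement.

## Propagation, relations, information content

Annotation propagation and consistency use `is_a` and `part_of` edges by
default. The hierarchy rule is stated in terms of subclasses only, but
GO practice treats `part_of` as annotation-propagating, so its inclusion
is a documented, configurable extension.

Information content is estimated from a propagated corpus as
$IC(c) = -\log \Pr(c \mid P(c))$ with the maximum-likelihood estimator
$\Pr(c \mid P(c)) = N(c) / N(P(c))$, where $N(c)$ counts proteins
carrying $c$ and $N(P(c))$ counts proteins carrying *every* parent of
$c$ (the corpus size for roots). The log base defaults to 2 (bits);
natural log is selectable. Classes with an undefined estimate (zero
numerator or denominator) fall back to the maximum observed IC — a
conservative choice that penalises predicting never-observed classes
without making the penalty infinite — and the fallback is logged.

## Evaluation

The sweep uses thresholds $t = 0.00, 0.01, \ldots, 1.00$ (101 points,
rounded to two decimals so grid values compare exactly against scores).
Per threshold: precision is averaged over the $m(t)$ proteins with at
least one prediction, recall over all $n$ evaluation proteins;
$F_{\max}$ is the maximum harmonic mean over thresholds with
$m(t) > 0$ (a threshold where precision and recall are both zero
contributes $F = 0$ rather than $0/0$). Remaining uncertainty $ru(t)$
and misinformation $mi(t)$ average the information content of missed
and spurious classes respectively, and
$S_{\min} = \min_t \sqrt{ru(t)^2 + mi(t)^2}$. AUPR is the trapezoidal
area under the protein-centric (recall, precision) points sorted by
recall. Ties in the best threshold resolve to the smallest $t$.
Namespace roots are excluded from evaluation sets by default, following
standard CAFA practice; evaluation is restricted to one namespace at a
time when the ontology has several, and proteins whose restricted truth
set is empty are dropped from $n$.

Every formula above is also implemented a second time in the test suite
as naive per-protein set arithmetic, and the two routes are required to
agree to $10^{-12}$ on hundreds of random instances.

## The synthetic benchmark

The generator emulates the pipeline's inputs end to end. The ontology is
a rooted tree per namespace (depth 2, branching 3 by default: 13
classes), optionally with extra parents to create genuine diamond-shaped
DAG motifs. Each leaf carries a unique random 8-residue motif; motifs
attach to leaves only, so internal classes gain sequence signal purely
through propagation — mirroring how specific functions drive sequence
signal while general ones are implied. Each of the 500 default proteins
draws one leaf class (two with probability 0.4), a background sequence
of 80–120 uniform residues, and implants each owned motif at a uniform
non-overlapping position with probability 0.9 — high enough that the
signal is recoverable, low enough that labels are noisy, the regime a
curated annotation corpus resembles. The hit simulator scores a
(query, training) pair by shared motif-length k-mers
(bitscore $= 25 \times$ shared k-mers $+$ Gaussian noise, SD 2, floor
10) and assigns e-values decreasing monotonically in bitscore
($10^{-\mathrm{bitscore}/4}$) so the e-value cutoff is exercised; over a
20-letter alphabet, background 8-mer collisions are vanishingly rare, so
unrelated pairs are absent.

What the generator does *not* emulate: homology at graded sequence
identity (hits are essentially binary motif matches), domain
architecture, taxonomic structure, inter-namespace correlations, or the
heavy-tailed class-frequency distribution of real GO corpora. Passing
the recovery tests therefore shows that the machinery is correct and
that the two routes genuinely learn from sequence — not that the
production-scale accuracy figures of a Swiss-Prot-trained model are
reproduced.

## Desk-scale study conditions

The end-to-end checks and `scripts/acceptance.R` run: 500 proteins
(400 train / 100 held-out queries), the 13-class ontology, implantation
probability 0.9, CNN vocabulary at `min_count` 20, and a toy CNN
(kernels {8, 16}, 32 filters, 128 encoded positions, 40 epochs, Adam at
0.01, batch 32) — sizes chosen so a full run trains in seconds on one
core while leaving the learning problem non-trivial. Expected outcomes:
similarity-only test Fmax $\ge 0.8$, CNN-only $\ge 0.6$, each at least
0.2 above a permuted-label control in which the same score matrix is
evaluated against a shuffled protein assignment (a retrained-on-permuted-
labels control would measure the same null at far higher cost). The
controls land around 0.4 rather than near 0 because even a shuffled
predictor recovers the frequent shallow classes — that is the label-prior
baseline the margin is measured against.

## Numerical and degenerate-input conventions

* OBO parsing rejects cyclic ontologies (naming the classes on the
  cycle) and edges to undefined terms; obsolete terms are recorded but
  excluded; `alt_id`s resolve silently to canonical ids, and obsolete
  ids inside annotation input are dropped with a warning.
* Sequences longer than `max_len` are truncated, not rejected — batch
  prediction should not fail on a long outlier; the limit is
  configurable.
* A query with no surviving hits yields an empty similarity score map,
  not an error; a zero total bitscore yields an empty map with a
  warning.
* Checkpoints (parameters, YAML config, vocabulary text) round-trip
  bit-exactly, and loading verifies parameter shapes against the stored
  config.

## Known limitations

Training is single-route CPU R/C++ and is not meant for Swiss-Prot
scale; there is no support for OBO constructs beyond `is_a`/`part_of`
(intersections, regulates), no micro-averaged or term-centric metrics
(AUPR is defined on the protein-centric curve), and no real aligner
integration in
the test path (the hit simulator stands in; the readers consume real
DIAMOND/BLAST tabular output unchanged).
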