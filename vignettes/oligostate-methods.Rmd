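---
title: "Predicting homo-oligomer subunit counts from sequence: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting homo-oligomer subunit counts from sequence: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oligostate)
```

## The problem

Most proteins function as oligomers, and for homo-oligomers the single
number that matters is NS, the count of identical chains in the assembled
complex: a homodimeric enzyme has twice the molecular weight its sequence
suggests, which propagates directly into enzyme-constrained metabolic
models and into the stoichiometry one must supply to complex-structure
predictors. Curated databases annotate NS as free text for only a fraction
of proteins. This package implements the full workflow for learning NS
from sequence alone: mining NS labels from UniProt-style XML, embedding
sequences through a pluggable encoder, and training a recurrent
attention classifier over ten NS classes
$\{1,2,3,4,5,6,7,8,10,12\}$.

## Label curation

UniProt records oligomeric state in a comment of type `subunit`, as prose
("Homooctamer of 4 homodimers; disulfide-linked..."), with ECO evidence
codes attached. The curation pipeline makes three passes:

1. **Parse.** `parse_uniprot_xml()` accepts namespaced or namespace-free
   documents, plain or gzipped. The streaming mode scans for complete
   `<entry>` elements, parses each and releases it, so memory is bounded
   by the largest entry rather than the file; a whole-document mode exists
   and the two are tested to agree field for field at several chunk sizes.
2. **Filter.** `filter_ns_evidence()` discards entries with no subunit
   description, entries whose comment evidence includes `ECO:0000250`
   (state inferred by sequence similarity, not experiment), and entries
   whose text hedges with "By similarity", "Probable" or "Potential".
   Each discard carries exactly one reason, assigned in that order, and
   the curation report obeys the conservation law
   `parsed = retained + sum(discards)`.
3. **Label.** `assign_ns_label()` applies a two-tier keyword table.
   Compound phrases such as "homooctamer of" fire first and decide the
   label immediately — the retinoschisin wording above must map to 8, not
   be torn between octamer and dimer. Otherwise a comment naming exactly
   one base keyword (`monomer`, `homodimer`, ..., `homododecamer`) gets
   that label; zero or several distinct base keywords leave the entry
   unlabeled and excluded, trading recall for label precision.

Design choices worth stating. The exact keyword table behind the published
datasets is not fully reproducible from the outside, so the package ships
a default table (`default_keyword_rules()`, also installed as
`extdata/default_rules.tsv`) built from the ten label names plus the
compound overrides; it is plain data and users can substitute their own
via `read_keyword_rules()`. Matching is case-insensitive on whole words
with optional plurals ("forms homotetramers" matches `homotetramer`).
Ambiguous multi-keyword descriptions are dropped rather than resolved by
precedence, since false labels are worse than fewer labels for training.
Fragment sequences are retained by default — the fragment flag is
orthogonal to the reliability of the subunit annotation — with
`drop_fragments = TRUE` available because fragments carry incomplete
sequence signal. `ECO:0000250` is tested only on the evidence attached to
the subunit comment, not on unrelated annotations of the entry.

## Embedding

The classifier consumes one pooled vector per protein. An
`encoder_backend` is any deterministic map from sequence to an
$l \times n$ per-residue matrix; the width the architecture is designed
around is $n = 1280$, the output width of the ESM2-class protein language
models. `pool_embedding()` collapses the residue axis by the arithmetic
mean (the usual choice for language-model classifier heads; max pooling
is provided as an option), giving the $1 \times 1280$ input $x$.

The package does not bundle a neural language model. All tests run on the
synthetic encoder: a seeded deterministic map from (residue, position) to
a Gaussian vector, optionally offset by a class center keyed to a hash of
the sequence. This preserves every contract that matters to the pipeline
— determinism, shape, sensitivity to point substitutions, class signal —
while being transparent about what it is not: it carries no evolutionary
information, so accuracy measured on it says nothing about accuracy on
real proteins. Precomputed language-model embeddings can be supplied
through the embedding store (`write_embedding_store()`, a self-describing
TSV recording backend, width and pooling).

## The classifier

With pooled input $x \in \mathbb{R}^{1\times1280}$ the model is

$$H_{gru} = f_{gru}(x), \qquad
  H_{att} = f_{att}(H_{gru}), \qquad
  Y = f_{fc}(H_{att}),$$

a bidirectional GRU (128 hidden units per direction; "128 hidden units"
is read as per-direction, so the concatenated width is $H = 256$),
multi-head self-attention with 32 heads (head width $H/32 = 8$), and a
fully connected softmax layer over the 10 classes. Training minimizes the
cross-entropy $H(p, q) = -\sum_x p(x)\log q(x)$ with $q$ clamped at
$10^{-12}$, using mini-batches of 1024 for 200 epochs at learning rate
0.001 and dropout 0.5 after the GRU and after attention.

Two degeneracies follow from pooling *before* the recurrence, and the
implementation reproduces them faithfully rather than papering over them:

* with a single timestep and a zero initial state, each GRU direction
  reduces to $h = (1-z)\odot\tanh(W_n x + b_n)$ with
  $z = \sigma(W_z x + b_z)$; the reset gate multiplies the zero previous
  state and vanishes, so it carries no parameters here;
* self-attention over a length-one sequence softmaxes over a single key,
  so every head's attention weight is identically 1 and the layer acts
  through its value and output projections only. The query/key
  projections are kept for architectural fidelity but provably receive
  zero gradient, and the head count does not change the function
  computed.

Choices the architecture description leaves open were fixed as follows
and are configurable: the optimizer is Adam (the standard companion to a
0.001 learning rate in this setting); weights start Glorot-uniform,
biases at zero; no early stopping, residual connections or layer
normalization; no class re-weighting or oversampling — a rare class such
as heptamers is allowed to fail and the macro metrics are designed to
show it. Everything random (initialization, shuffling, dropout) descends
from one integer seed, so training is bit-reproducible; the forward and
backward passes are hand-written matrix arithmetic, verified in the test
suite against an explicit scalar oracle and against finite-difference
gradients.

## Evaluation

`confusion_counts()` builds one-vs-rest counts per class;
`macro_metrics()` averages per-class accuracy, precision and recall with
equal class weight and combines the macro averages harmonically into mF1.
Two conventions for macro-F1 circulate — the harmonic mean of
mPrecision and mRecall, and the mean of per-class F1 scores — and
published fold tables for this task mix them; the harmonic form is
primary here (it reproduces the self-consistent published folds to three
decimals) and the per-class average is reported alongside as
`mF1_per_class`. A per-class precision or recall with an empty
denominator contributes 0 and the class stays in the average: a class the
model never gets right must drag the macro score down, not vanish.
The one-vs-rest construction implies the identity
$mACC = 1 - 2(1 - \mathrm{accuracy})/N$, which the suite checks in
exact arithmetic.

Model selection follows the reference protocol: a seeded 8:2
train/test split (`train_test_split()`) and 10-fold cross-validation
(`cross_validate()`) in which folds are random rather than stratified —
matching the stated protocol — with a `stratified` option since random
folds can starve a 14-sample class. The summary row reports the mean and
the sample standard deviation ($n-1$) per metric, the convention that
reproduces the published ± columns.

## Dataset characterization

`label_distribution()` tabulates NS counts, optionally per organism.
`ec_ns_diversity()` groups proteins by EC number and counts distinct NS
labels per EC — the enzymes topping this table (superoxide dismutases,
DNA polymerases, inorganic diphosphatases) genuinely adopt different
stoichiometries across organisms, which is one reason sequence similarity
alone cannot settle NS. `pairwise_identity()` aligns proteins sharing an
EC number and records percent identity against label agreement. The
alignment scheme is not dictated by the task, so the package fixes a
documented default: Needleman–Wunsch global alignment under BLOSUM62 with
affine gaps (open 10, extend 0.5, a length-$k$ run costing
$10 + 0.5k$), identity defined as identical aligned positions over the
alignment length, gaps included. The aligner is Biostrings'
dynamic-programming implementation; the suite checks it against an
exhaustive enumeration of all alignments on short sequences. All-vs-all
alignment within an EC group is quadratic, so pairs are sampled up to a
seeded cap.

## Synthetic data: what it shows and what it cannot

`fixture_spec()` fixes the study conditions for every synthetic run:
class centers drawn once from a standard Gaussian in `width` dimensions
(pairwise distances concentrate near $\sqrt{2\,\mathrm{width}}$),
`n_per_class = 30` points per label as center plus isotropic noise,
`noise_sd = 0.1` — a wide-margin regime in which nearest-centroid
classification is provably perfect, so a trained classifier below 0.95
held-out macro-accuracy indicates an implementation bug, not hard data.
The sequence generator draws random 50–100-residue sequences and assigns
the hidden class by the same sequence hash the synthetic encoder uses, so
the FASTA → embed → train → predict path can be tested end to end with
known ground truth. None of this emulates real signal: cluster geometry
is isotropic where language-model embeddings are anisotropic, classes are
balanced where real NS labels are dominated by monomers and dimers, and
the class signal is planted rather than learned from evolution. Passing
these tests certifies the machinery, not biological accuracy.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run at reduced width
(32 instead of 1280), hidden size 16, batch 256, and 300 synthetic
samples — sizes chosen so the full suite exercises every code path,
including 10-fold cross-validation with training per fold, in well under
a minute on one CPU; the 1280-width shape contract is exercised once.
Ties in the predicted distribution break toward the smaller NS label (a
documented, deterministic rule). Probabilities are clamped at $10^{-12}$
inside the loss; softmax subtracts the row maximum before
exponentiation; a non-finite training loss aborts with diagnostics
rather than continuing silently.

## Known limitations

The keyword table is a documented reconstruction, not the authors' exact
appendix; descriptions that encode NS in uncommon wording are left
unlabeled. The degenerate pool-then-recur architecture is reproduced as
specified — an optional recur-then-pool variant would use the sequence
axis but is deliberately out of scope. Training is plain R matrix
arithmetic: ample for the reduced-width study conditions and for
moderate datasets, but not for GPU-scale retraining on a full database
release. Release-dependent database counts and the headline accuracy of
the published full-scale model require the full Swiss-Prot corpus and a
language-model encoder, and are therefore documented rather than
asserted by the tests.
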