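---
title: "Scoring in-frame indels with overlap-restricted language-model probabilities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring in-frame indels with overlap-restricted language-model probabilities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(indellm)
```

## The problem

An in-frame insertion or deletion changes a protein's length by whole
residues. Protein language models (PLMs) expose, for every position $i$ of a
sequence $s$, a distribution $P(x_i = a \mid s)$ over the 20 amino acids, and
the pseudo-log likelihood

$$\mathrm{PLL}(s) = \sum_{i=1}^{L} \log P(x_i = s_i \mid s)$$

is the standard zero-shot sequence score. The natural effect score for a
variant, $\mathrm{PLL}(s_\mathrm{mut}) - \mathrm{PLL}(s_\mathrm{wt})$,
compares sums with *different numbers of terms* whenever the variant is an
indel: every extra residue contributes another negative log term, so the
score drifts with indel length regardless of pathogenicity. On top of that,
poorly conserved regions receive low probabilities in both sequences, and on
the log scale those positions dominate the difference.

This package scores the *overlap region* instead — the residues present in
both sequences — and sums raw probabilities rather than logs:

$$\mathrm{score} = \sum_{i \in \mathrm{overlap}} P(x_i = s_i \mid s_\mathrm{mut})
                 - \sum_{i \in \mathrm{overlap}} P(x_i = s_i \mid s_\mathrm{wt}).$$

Both sums have exactly $\min(L_\mathrm{wt}, L_\mathrm{mut})$ terms, so the
length bias vanishes, and the bounded per-position contributions
$d_i \in [-1, 1]$ damp conservation noise. Because the PLM is context aware,
the indel's effect is visible in the marginals of the *surviving* residues.
The five methods shipped (`score_variant()`) are the full-sequence PLL
difference (`brandes`), the overlap probability difference (`indellm`),
their absolute values, and the overlap score computed from per-position
masked marginals (`indellm_masked`). The acceptance suite verifies the bias
property directly: with i.i.d. synthetic probabilities the PLL difference
grows in magnitude with deletion length (by $-\mathbb{E}[\log p]$ per
residue) while the overlap score stays centred at zero.

## Variant normalization

Scoring needs a well-defined overlap bijection, so sequence-only input is
normalized by `infer_indel()`: a longest-common-prefix /
longest-common-suffix scan locates the single contiguous indel, and when a
repeat makes the placement ambiguous the **leftmost** placement is chosen.
This is a package convention, chosen because it is deterministic and matches
the usual left-alignment convention for variant normalization; any explicit
annotation supplied with the data takes precedence (after a consistency
check), so externally curated positions survive round trips. Every placement
of an indel inside a repeat yields the same overlap multiset of residues, so
the choice does not change scores, only reported coordinates.

Nonstandard letters (X, U, B, Z) are accepted with a warning; they have no
probability column, so any overlap pair touching one is excluded from *both*
sums — paired exclusion keeps the two sums comparable, which is the whole
point of the method.

## Long sequences

Transformer PLMs cap input length, so sequences longer than 1,000 residues
are truncated around the indel (`crop_variant()`): up to 500 residues are
kept on each side of it, giving crops of at most 1,000 + indel length. If
2·500 + indel length would exceed the 1,022-residue model capacity, the
flanks shrink symmetrically so the longer crop is exactly 1,022 (the
upstream flank takes the odd residue). Near a terminus the missing flank is
clipped, **not** transferred to the other side: transferring would keep more
context but make the two crops' flanks differ, and identical flanks are what
keeps the cropped overlap map a shifted restriction of the full one (a
property the tests check). The trigger for flank reduction is the crop
exceeding capacity, and an indel of ≥ 1,022 residues has no valid crop and
is an error. All three parameters are user-facing (`--max-len`, `--buffer`,
`--model-cap`).

## Backends

Scoring is written against a minimal provider contract (`plm_provider`):
`marginals()` (one unmasked forward pass, softmax over the 20 canonical
letters), `masked_marginals()` (row $i$ from a pass with position $i$
masked — $L$ passes), and `embed()` (last-hidden-layer per-residue
embeddings, special tokens excluded so rows align 1:1 with residues; mean
pooling therefore never mixes in BOS/EOS states, an assumption recorded
here). Backends with larger vocabularies must renormalize mass over the 20
canonical columns. `cached_provider()` memoises per sequence (optionally on
disk) so scoring and feature building never recompute a forward pass — the
masked mode is $L$ times the cost of the unmasked one, which is why the
unmasked variant is the default.

The shipped backend is the deterministic synthetic provider: per-position
distributions are normalized gamma draws (concentration 0.5) with the
observed residue's cell boosted so observed probabilities sit in a realistic
mid range, all derived from a 31-bit hash of (seed, sequence) so outputs are
bitwise reproducible and independent across sequences. Masked marginals are
the unmasked matrix under a bounded multiplicative jitter (at most 0.05 per
cell, renormalized): distinct but strongly correlated, which is how the two
scoring modes behave on real models. A real-model adapter plugs in through
`register_backend()` without touching any scoring code.

## The synthetic study conditions

`generate_labeled_dataset()` emulates the statistical structure of a curated
clinical indel set: sequence families (ancestors mutated at 10–40% of
positions) so identity clusters exist and leakage is possible if splitting
ignores them; 32% insertions; indel lengths 1–10 with geometrically decaying
weights (so roughly three quarters are the 1–2-residue "short" class, as in
clinical collections); 40% pathogenic. Pathogenic variants receive signal
through two independent, separately switchable channels:

* **probability depression** (`effect_size`): mutant observed probabilities
  within 10 residues of the indel are scaled down — the signature zero-shot
  scoring detects;
* **embedding shift** (`embedding_shift`): a fixed offset on the indel-region
  embedding rows — invisible to probability scores, detectable only by an
  embedding classifier that looks at the indel region.

With both channels at zero, labels are independent of everything generated
and every detector must collapse to chance. What the generator does *not*
emulate: real ESM2 probability statistics (conservation gradients, secondary
structure periodicity), correlated probabilities between wild-type and
mutant contexts, or biologically plausible sequences. Green tests therefore
demonstrate algorithmic correctness and recoverability of planted signal at
realistic sample sizes — not clinical performance, which requires real model
weights and curated data.

## The Siamese classifier

Transfer learning uses frozen embeddings and a deliberately small network:
one shared hidden layer of 8 units (linear $D \to 8$, LeakyReLU, dropout 0.5
at train time) applied with **tied weights** to each sequence representation
("Siamese"), branch outputs concatenated with any scalar inputs into a
2-node softmax head, trained with cross-entropy and Adam, early-stopped on
validation AUC with the best-epoch checkpoint restored. Four feature
configurations (`build_features()`):

1. mean embeddings of the full wild-type and mutant sequences;
2. model 1 plus the overlap probability score;
3. model 2 plus indel type (0 = deletion, 1 = insertion) and length;
4. mean embeddings of the *overlap* regions of both sequences, the mean
   embedding of the indel residues of the longer sequence, plus type and
   length.

Two fusion details are genuinely open design territory and are resolved
here as follows. Scalars bypass the hidden layer and enter the head
directly: under weight tying an 8-unit encoder sized for $D$-dimensional
embeddings cannot also consume 1–2 raw numbers. And scalars are standardized
on the training split (indel length is log1p-transformed then z-scored;
the probability score z-scored), because raw lengths up to hundreds of
residues would otherwise dominate the concatenation. Default
hyperparameters — batch 64, learning rate $10^{-3}$, negative slope 0.01,
patience 10, 200 epoch cap — are package defaults tuned for the synthetic
recovery experiments and exposed through `siamese_hyperparams()` and
`grid_search()` (exhaustive, ties toward smaller learning rate then smaller
batch). Replicate reliability is assessed by `replicate_runs()` (seeds
`base_seed + 0..k-1`, metrics reported mean ± sd). The decision threshold on
the pathogenic-node probability defaults to 0.46, the published operating
point of the corresponding clinical model; on synthetic data it is close to
optimal because classes are near-balanced, but `optimal_threshold()` refits
it when needed.

## Splitting and evaluation

`assign_splits()` distributes identity clusters (CD-HIT `.clstr` output via
`parse_clusters()`, or the k-mer fallback for synthetic data) over
train/validation/test at 80/10/10 while keeping every cluster whole. The
allocator is a seeded greedy pass: clusters are shuffled, then each goes to
the split with the largest remaining deficit over the eight
type × size × label strata, deficits normalized by the target fraction so
the 10% splits compete with the 80% one. The stated constraints (random,
cluster-atomic, near-equal stratum fractions) admit many algorithms; this
one is simple, $O(\text{clusters} \times \text{strata})$, and achieves mean
per-stratum deviations under 1 percentage point on 1,000-record synthetic
data (the acceptance suite averages over 100 seeds).

Metrics (`mcc()`, `f1()`, `roc_and_auc()`, `optimal_threshold()`) follow the
standard definitions with pathogenic as the positive class; MCC returns 0 on
a zero marginal, ROC thresholds are the observed score values with tie
groups flipping together, AUC is the trapezoid (equal to pairwise
concordance with half credit for ties, verified against brute force and
against pROC), and the optimal threshold maximizes Youden's $J$ under the
same strict-inequality classification rule used everywhere
(`classify()`: pathogenic strictly below threshold for signed scores, ties
benign). Ties in $J$ break toward lower FPR, then fewer pathogenic calls —
a documented package convention.

## Interpretability

`residue_difference_track()` emits
$d_i = P(x_i = s_i \mid s_\mathrm{mut}) - P(x_i = s_i \mid s_\mathrm{wt})$
for every overlap pair; each $d_i \in [-1, 1]$ and the track sums *exactly*
to the variant's overlap score, so it is a faithful per-residue
decomposition of the prediction, reported in both sequences' coordinates and
de-cropped to full-sequence positions. `annotate_structure()` writes the
clamped differences into the B-factor column of a PDB chain (matching by
residue number plus a user offset — no re-alignment, so numbering gaps are
the user's responsibility and insertion codes are rejected with a warning),
with 0.00 for uncovered residues and the sentinel 9.99 for deleted residues
present in the structure. A diverging colour map at roughly ±0.2 is a
sensible visualization default; the data are never thresholded.

## Numerical conventions and limitations

Natural logs throughout (the base only rescales PLLs, and ROC-derived
thresholds are invariant to the choice for a fixed base). Signed scores are
oriented lower-is-pathogenic — a damaging variant lowers the mutant's
likelihood — which is also the orientation implied by the negative default
threshold (−0.59, the published ROC-optimal operating point of the overlap
score); absolute variants are higher-is-pathogenic. A probability of exactly
zero inside a PLL restriction raises an error rather than being floored:
silent $\log 0$ handling hides backend pathologies, and well-formed softmax
outputs are strictly positive. Exact threshold ties are called benign.

Out of scope by design: multi-site and mixed substitution/indel variants,
frameshifts, nucleotide coordinates, sliding-window scoring of ultra-long
proteins, PLM fine-tuning, and mmCIF structures. Test problem sizes — 1,000
random variants for oracle equivalence, 400-record recovery experiments,
1,000 records × 100 seeds for split balance — were chosen so the full suite
exercises every property at statistically meaningful scale while remaining
quick on a laptop.
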