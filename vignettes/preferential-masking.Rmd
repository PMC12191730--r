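---
title: "Preferential CDR3 masking for paired antibody language models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Preferential CDR3 masking for paired antibody language models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Masked language models (MLMs) of antibody sequences are trained by hiding a
random subset of residues and predicting them from bidirectional context.
Under the conventional scheme every residue is selected independently with
probability 15%. Antibody variable domains, however, are mostly
germline-templated: the four framework regions (FR1–FR4) and, to a lesser
degree, CDR1 and CDR2 are copied from a small set of V(D)J gene segments,
while the CDR3 — the loop spanning the V(D)J junction — is partly
non-templated and carries most of the sequence diversity. Uniform masking
therefore spends most of its training signal on easily predicted templated
positions.

`abmlm` implements and probes the alternative: *preferential masking*, which
raises the masking probability in both chains' CDR3s and rescales the
probability everywhere else so the sequence-average rate is unchanged.

## The masking model

For an encoded heavy/light pair, let `p_hat` be the fraction of residue
positions lying in either CDR3. Each residue position gets masking
probability

* `r_cdr3` (default 0.25, with 0.35 supported as a high-rate variant) if the
  position is in a CDR3, and
* `(r_avg - r_cdr3 * p_hat) / (1 - p_hat)` otherwise, with `r_avg = 0.15`,

so the mean over residue positions is exactly `r_avg`: a model trained this
way sees the same *amount* of corruption as a uniformly masked model, but
CDR3 positions carry `r_cdr3 / r_avg ≈ 1.67x` the training signal. Special
tokens and padding are never masked, and the 15% average is defined over
residue positions only (masking a separator is never meaningful). For
extreme CDR3 fractions (`p_hat >= r_avg / r_cdr3`, i.e. 0.6 at the default
rates) the non-CDR3 expression would go negative; such plans are clamped to
zero outside the CDR3 and flagged, accepting an above-target average for
those records. The non-CDR3 probability is computed as
`r_avg + (r_avg - r_cdr3) * p_hat / (1 - p_hat)`, an algebraically identical
form chosen so that setting `r_cdr3 = r_avg` reproduces the uniform plan
bit-exactly.

Masking plans depend only on a record's region layout, so they are computed
in one pass over a dataset, cached (`build_plan_cache()`), persisted with a
manifest, and reused every epoch; a cache read under a different strategy,
rate, or dataset fails loudly rather than silently reusing stale
probabilities.

Corruption itself is dynamic (`collate_batch()` and the trainer's internal
collator): every batch re-draws selected positions from the plan; of the
selected positions 80% become `<mask>`, 10% become a random residue token,
and 10% are left unchanged. Random replacements are drawn from the 21
residue tokens only — drawing a special token would corrupt the chain
layout, a deliberate restriction of "random token from the vocabulary".

## Tokenization

The vocabulary has 26 tokens: the 20 canonical amino acids, `"X"` for
unnatural residues (unknown characters map to `"X"`, not `<unk>`), and
`<pad>`, `<mask>`, `<unk>`, `<cls>`, `<eos>`. A pair is encoded as `<cls>`,
heavy residues, `<cls><cls>`, light residues, `<eos>`, padded to 320. The
double `<cls>` is the chain separator; the leading `<cls>` and trailing
`<eos>` follow the conventions of the encoder family this architecture
belongs to and are isolated in the encoding layout so they are testable and
swappable.

## The synthetic repertoire

No real repertoire ships with the package; `simulate_repertoire()` generates
paired records with the statistical structure the method cares about:

* **Germline templating.** Random V/D/J segment libraries with FR1 ≈ 25,
  CDR1 ≈ 8, FR2 ≈ 17, CDR2 ≈ 8, FR3 ≈ 38, FR4 ≈ 11 residues (small
  per-segment jitter), the lengths of IMGT-numbered human variable domains.
* **Junctional diversity.** CDR3 = geometrically trimmed V tail (+ trimmed D
  on the heavy chain) + Poisson-many uniform non-templated insertions +
  trimmed J head; trimming that would empty the CDR3 is resampled. These are
  the simplest processes that give variable-length, high-entropy CDR3s.
* **Coupled mutation loads.** Each memory cell draws one latent maturation
  intensity (Gamma, shape 2, mean `mutation_rate_scale = 8` heavy-chain
  mutations — a mid-range memory load); the heavy chain receives
  Poisson(intensity) mutations and the light chain Poisson(0.8 × intensity).
  The shared intensity makes native pairs' mutation counts strongly
  correlated and the 0.8 factor makes lights less mutated, without extra
  parameters. Neither the correlation strength nor the heavy/light
  asymmetry is quantified in published repertoire statistics at the
  resolution the simulator needs, so the coupling here is a free modeling
  parameter, not a fitted one. Mutations land on CDR positions with weight
  `cdr_hotspot_weight = 3`.
* **Cell types and donors.** Naive/memory is a per-record
  Bernoulli(`naive_fraction`); naive cells carry zero mutations. Donors are
  independent replicate streams of one generative process (no donor-specific
  germline variation). Mixed naive/memory same-donor datasets and
  memory-only held-out-donor datasets are both single configuration choices.
* **Specificity labels.** Positive-class records carry a residue motif
  (default `WGRDY`) implanted at a random offset inside the heavy CDR3 with
  probability `motif_implant_prob`; this is the simulator's mechanism for a
  learnable class signal, standing in for the recurring binding motifs of
  real specificity datasets.

What the simulator deliberately does *not* emulate: nucleotide-level
recombination, AID hotspot motifs, allele frequencies, isotypes, germline
polymorphism, or the phylogenetic clonal structure of real repertoires.
Passing tests on this generator show that the masking, training, evaluation
and attribution machinery behaves as specified under realistic sequence
statistics — not that any biological conclusion transfers to real data.

## Encoder and training harness

The encoder is a pre-layer-norm transformer with rotary position embeddings
and a tied masked-language-model head, written in single-precision
RcppArmadillo with hand-derived backward passes (no deep-learning framework
is involved). Two presets exist: `paper_350m` (32 layers, 20 heads, hidden
960, intermediate 3840 — constructible and countable, never trained in
tests) and `tiny` (2 layers, 4 heads, hidden 64, intermediate 256), the
desk-scale default. Training uses AdamW (β = 0.9/0.98, ε = 1e-8, weight
decay 0.01 on weight matrices only — these are configuration, not contract),
a linear warmup then linear decay schedule, and cross-entropy over selected
positions only. The tiny schedule is 2000 steps at batch 8, peak learning
rate 1e-3, 100 warmup steps, checkpoints every 500 steps; batch 8 is the
package's single-CPU problem size. Runs are exactly reproducible from their
seed.

Numerical choices worth knowing about: softmax and GELU use a branch-free
polynomial `expf` (~1e-7 relative accuracy) and the tanh form of GELU so the
compiler can vectorize them; attention scores are stored key-major so the
softmax runs down contiguous columns; gradients were verified against
central finite differences (truncation-dominated convergence, and the
attribution gradient matches a five-point stencil to 1e-4 relative to the
largest component).

## Validation and evaluation

Preferential masking makes the *training* task harder, so comparing
training losses across strategies would be unfair. Validation loss is
therefore always computed under uniform masking, and additionally from
masks drawn once with a fixed seed, so both strategies are scored on
bit-identical masked positions. Each masked position's loss is assigned to
its chain-agnostic region bucket (FR pools all eight frameworks, CDR1,
CDR2, CDR3 pool both chains); the overall loss is the target-count-weighted
mean of the buckets, and empty buckets at tiny scale are reported absent,
never as zero. Checkpoint selection takes the lowest overall validation
loss, earliest on ties.

Per-position inference (`per_position_accuracy()`) masks exactly one
position per forward pass — single-token corruption, not the 80/10/10
collator — and compares the argmax over residue tokens (predicting a
special token is never counted correct) against the truth, aggregated per
sequence over the 14 chain-qualified regions. Records split into cohorts by
V-gene mutation count; a pair counts as "mutated" if either chain carries V
mutations — cohort definitions vary between repertoire studies, and this
one is the package's rule. Two models are compared per region by a
two-sided paired t test
with Bonferroni correction for the 14 region hypotheses.

## Classifier tasks

`make_shuffled_pairs()` builds the native-vs-shuffled pairing task: within
each donor a random half of the pairs have their light chains permuted by a
derangement (a plain permutation could hand a chain back to its own
partner), shuffled pairs that recreate a native heavy/light combination via
light-chain redundancy are filtered and counted, and the class balance is
restored exactly by trimming the excess. Heads are single affine maps (2
logits) trained on pooled embeddings from a frozen base — frozenness is
asserted by checksum — under 5-fold stratified cross-validation with
rotating fold assignment so fold sizes differ by at most one; every score is
produced by the head that did not see that record in training. Pooling is a
config: the leading `<cls>` state or the mean over residue positions.
Metrics are accuracy, AUC, AUPR (average precision), F1 and MCC, reported
per fold with mean ± SE over the 5 folds. Mutation-count grids tabulate
predictions by (heavy, light) V-mutation counts for native and shuffled
truth separately.

## Attribution

`attcat_scores()` implements gradient-based token attribution for the
classifier: for layer *l* and token *i*, the component is the inner product
of the layer's input hidden state with the gradient of the target-class
logit with respect to it, weighted by the mean attention received by token
*i* in that layer (averaged over heads and query positions — the reference
method admits variants; this aggregation is the package default and
pluggable), summed over layers. Raw impact is positive toward the target
class; the display scores negate it so negative = toward the class, and
standard scaling (population mean 0, sd 1 per sequence, with a flag against
double application) makes scores comparable across models. Early-sequence
attention-sink tokens are not removed, only visible in the attention
summaries. `select_explanation_cohort()` picks k records evenly across the
rank range of mean predicted probability, ascending, ties broken by record
id.

## Problem sizes and what the desk-scale results mean

The package's standing experiment sizes, chosen once as single-CPU
conditions: repertoires of 120–2000 pairs, the tiny encoder preset, 2000
training steps at batch 8 for strategy comparisons (three seed pairs,
shared data and validation masks), a few hundred steps for bases used in
classifier tests, and 1000-pair round-trip checks for the tokenizer. At
this scale the uniform-vs-preferential comparison is a directional
replication: preferential masking should achieve equal-or-lower CDR3
validation loss at the matched final step in most seed pairs. Full-scale
effects (convergence-speed percentages, real-repertoire pairing accuracy,
real specificity classification) are out of reach of a tiny model on
synthetic data and are not claimed.

### A note on the specificity ceiling

With implant probability `q < 1`, a fraction `1 - q` of positive records
carry no motif and are statistically identical to negatives, so no
classifier can exceed AUC `q + (1 - q)/2` in expectation (0.9 at the
default `q = 0.8`). Tests that demand near-perfect separability therefore
run the generator at `q = 1`.

A second, sharper ceiling concerns the base model. A mean-pooled
representation of an MLM-trained base sees the motif as a ~5-residue
perturbation of a ~250-residue composition; the composition noise of the
other positions caps linear separability near AUC 0.7 unless the base has
learned the motif's *context* during pre-training, which at tiny scale it
does only slowly (measured: AUC ≈ 0.68 after 3000 steps, ≈ 0.76 after
6000). The package therefore ships `motif_probe_base()`, a
hand-parameterized one-layer encoder that exposes the motif by
construction: content-free rotary query/key biases pin each attention head
to a fixed relative offset (−2, −1, +1, +2), head values indicate whether
the attended token matches the motif residue expected at that offset, and
the feed-forward block thresholds the sum of the four neighbor indicators
plus the center-residue identity — an AND gate over the full 5-mer whose
threshold follows in closed form from the layer-norm arithmetic of the
one-hot embedding. The final layer-norm gain keeps only the gate's output
dimension, so the mean-pooled state essentially counts motif occurrences.
Head-training and attribution checks that require near-perfect
separability use this base; it is the package's concrete instance of
"embeddings that expose the class signal", with ground truth known
exactly.

## Known limitations

* Single precision throughout the encoder; losses match double-precision
  references to ~1e-5 relative, not bit-exactly.
* The greedy identity clustering is order-deterministic but not globally
  optimal, matching common repertoire-tool semantics (identity = matches /
  global-alignment length, gaps count against identity) rather than exact
  clustering.
* The simulator's mean-pooled class signal for short implanted motifs is
  weak by construction (a ~5-residue needle in a ~250-residue haystack);
  separability depends on the base model having learned the motif context
  during pre-training.
* `paper_350m` is provided for architecture arithmetic (parameter counts,
  shapes); training it is outside the package's scope.
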