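---
title: "Desk-scale autoregressive language modelling of RNA sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Desk-scale autoregressive language modelling of RNA sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnalm)
library(Biostrings)
```

# The model

`rnalm` treats RNA as a language. A sequence is encoded into tokens
$x_1, \dots, x_L$ (each token covering one or more nucleotides) and modelled
autoregressively,

$$p(X) = \prod_{i=1}^{L} p(x_i \mid x_{<i}),$$

by a decoder-only transformer: learned token embedding (tied with the output
projection), learned absolute positional encoding, and pre-normalisation
blocks of causal multi-head self-attention followed by a GELU feed-forward
network. Training minimises the negative log-likelihood (NLL)

$$\mathrm{NLL}_{\mathrm{seq}} = -\sum_{i=1}^{L} \log p_\theta(x_i \mid x_{<i}),$$

reported per token in nats; perplexity is `exp(per-token NLL)`. The forward
and backward passes are written directly against R's BLAS-backed matrix
algebra, so the whole training loop is inspectable R code with no external
deep-learning runtime; a finite-difference check in the test suite verifies
every gradient path.

Two configurations are built in. The **desk configuration** (2 layers, model
dimension 64, 4 heads, context 64 tokens) is the default everywhere: it is
the largest configuration whose full training loop stays in the minutes
range on one CPU in pure R while still exercising multi-head attention,
residual blocks and the tied output head. The **publication-scale preset**
(`paperScaleConfig()`: 24 layers, dimension 1280, context 1024, vocabulary
1024) is recorded for reference and parameter-count inspection but never
instantiated by the package's tests or examples — the desk artifact
re-implements the method, not the scale.

Initialisation follows the usual convention for this architecture family:
linear-layer weights are Kaiming (He) draws, embedding and positional
weights are Gaussian with mean 0 and standard deviation 0.02. LayerNorm
gains and biases start at 1 and 0 — initialising them from the same 0.02
Gaussian would cripple optimisation, so the 0.02 rule is read as applying to
the embedding-like weight classes only. Biases start at 0.

# Tokenization

Byte-pair encoding is trained directly on the nucleotide alphabet: the most
frequent adjacent token pair is merged iteratively until the target
vocabulary size is reached or no pair occurs at least twice. Sequences are
never merged across the end-of-sequence (EOS) delimiter, which is always
token id 0; there is no beginning-of-sequence token. Ties in pair frequency
break lexicographically on the concatenated string, so tokenizer training is
fully deterministic without a seed. IUPAC ambiguity codes are ordinary base
symbols; they are rare, so they rarely merge. The desk vocabulary is 64
tokens; the publication-scale preset is 1024, and the acceptance checks
train a 1024-token vocabulary on a synthetic corpus to confirm the trainer
reaches it. Encoding applies merges in rank order, leftmost occurrence
first, which reproduces the training segmentation; `decode(encode(s)) == s`
for any sequence over the training symbols.

# Training

Pre-training uses Adam ($\beta_1 = 0.9$, $\beta_2 = 0.999$) with a linear
warmup from 0 to 1e-3 over the first 0.67 epoch and a linear decay to 1e-4
at the last step. Fine-tuning uses a constant 1e-4 with no warmup or decay.
Gradients are clipped at global norm 1.0 (switchable); the clip mainly
protects the first few steps. The training stream concatenates
EOS-terminated encoded sequences in a seeded order and chunks them into
context-length blocks; the final partial block is EOS-filled with the fill
excluded from the loss, so every real token contributes exactly once per
epoch. Validation NLL is computed under the same chunking convention, which
keeps train and validation losses directly comparable.

Batch size defaults to 16 blocks and weight decay is not used; both are
desk-scale choices the source recipe leaves open. Early stopping (used by
the ablation preset with patience 3) tracks validation NLL per epoch and
returns the best-validation checkpoint.

# Generation

All decoding strategies run through one generic, `nextTokenLogProbs()`, so
they work identically on trained transformers and on hand-specified
`tableModel()` toys (which is how the decoders are tested against exhaustive
enumeration). Decoding starts from `[EOS] + encode(prefix)` and stops at EOS
or a length cap (capped outputs carry a `truncated` attribute):

- **Greedy** takes the argmax token each step.
- **Beam** expands each live hypothesis over the whole vocabulary, keeps the
  top `beamWidth` candidates by summed log-probability (no length
  normalisation), freezes candidates that emit EOS, and returns the best
  completed hypothesis; ties break toward the smaller token id sequence.
  Width 1 reduces exactly to greedy.
- **Top-k** divides logits by the temperature, renormalises the k most
  probable tokens and samples. `topK = 1` is greedy; as the temperature
  approaches 0 the sampler converges to greedy.

Because greedy and beam are deterministic, batches for those strategies are
driven by enumerating all $4^{\ell}$ nucleotide prefixes of length $\ell$
(default 5, giving the canonical 1,024 sequences); stochastic batches are
independent seeded draws from the empty prefix.

# Evaluation statistics

**k-mer spectra and KL divergence.** k-mer counts use a 1-nt sliding window
over all $4^k$ words (windows containing ambiguity codes are skipped —
`Biostrings::oligonucleotideFrequency` implements exactly this policy). The
divergence between generated (P) and reference (Q) spectra is
$\sum_i P(i)\,\ln(P(i)/Q(i))$ in natural-log units. The source formula
leaves the log base and the handling of empty cells unstated, so the package
fixes both: nats, and a pseudocount (default 1) added to both count vectors
before normalising; with `pseudocount = 0` an infinite divergence is
returned flagged rather than silently smoothed.

**k-let-preserving shuffle.** The composition control shuffles a sequence
while preserving its exact multiset of k-mers (default k = 3). The
implementation is the exact construction: a random Eulerian walk on the
(k-1)-mer de Bruijn multigraph whose last-exit arborescence is drawn
uniformly with Wilson's loop-erased random-walk algorithm, giving a uniform
draw over all valid shuffles. A brute-force permutation oracle in the test
suite confirms both validity and coverage of the valid set on short strings.

**Folding backend.** Structure scores come from a pluggable backend. The
built-in backend is a Nussinov-style weighted base-pair maximisation
(G:C = 3, A:T = 2, G:T = 1, minimum hairpin loop 3, ambiguity codes forced
unpaired) solved by O(n^3) dynamic programming with traceback, reported
negated so lower = more stable. These are arbitrary energy-like units, *not*
a thermodynamic nearest-neighbour model: scores are comparable only within a
backend, which is sufficient for the within-backend group comparisons below.
A thermodynamic engine can be registered with `registerFoldBackend()`.

**The four-group control experiment.** Around a set of generated sequences,
`mfeGroupExperiment()` builds length-matched controls: natural sequences
sampled to the same 50-nt length histogram, per-sequence uniform-random
controls, and the k-let shuffle of each generated sequence. Group
differences are tested with rank-sum tests (normal approximation):
two-sided for generated vs natural, one-sided (generated lower) against the
shuffled and random groups. `binnedLowerMfeFraction()` reports, per length
bin, the fraction of sequences strictly more stable than their own shuffle;
ties count as not-lower, and empty bins are reported missing rather than 0.
On designed GC-stem hairpin fixtures the expected ordering
generated < shuffled < random is reproduced; on random sequences the
fraction sits near 1/2 by exchangeability (short sequences tie often, which
depresses the fraction — the package reports the fraction as defined).

**Novelty search.** Queries are classified against a database by
seed-and-extend local alignment: candidate targets must share an exact word
(default 7 nt), extension scoring is match +1, mismatch −1, gap opening 2,
gap extension 1 (the Smith-Waterman engine is
`Biostrings::pairwiseAlignment`; an independent pure-R Gotoh oracle checks
it on small instances). Identity is $100 \cdot n_{\mathrm{identical}} /
n_{\mathrm{align}}$ over the aligned columns. Significance is an empirical
e-value calibrated on k-let-shuffled decoy queries — the expected number of
decoys reaching a score, scaled to the query-set size — with threshold 0.1.
This deliberately simple scheme replaces a profile-HMM search; its
sensitivity is not comparable to one, and the classification
(identical-hit / partial-hit / no-hit) should be read per-backend, like the
fold scores.

**Deduplication.** Corpus deduplication is greedy representative clustering
at 80% identity. Identity is matches / alignment columns of the best local
alignment, and a removal additionally requires the alignment to cover at
least 80% of the shorter sequence. The coverage requirement matters: the
best-scoring *local* alignment between two unrelated sequences is typically
a short near-perfect match whose column identity is ~100%, so uncovered
local identity alone would collapse unrelated records; production clusterers
impose the same kind of coverage constraint for the same reason.

# The binder workflow and its ablation

The fine-tuning demonstration runs entirely on synthetic data. Background
sequences come from a seeded Markov generator (order 0-3); positive
("binding") sets implant a PWM-sampled motif instance at a uniformly random
offset, *overwriting* w positions so lengths stay comparable; negatives are
pure background. The default demonstration uses 200 positives and 200
negatives of 40-60 nt with an 8-nt implanted motif — small enough to run in
minutes, large enough for the 60/30/10 curation split to leave ≥50
sequences per scorer class.

Curation deduplicates each label at 80% identity, splits positives
60/30/10 into generator-fine-tuning / scorer-training / test partitions
(largest-remainder rounding, so round totals split exactly), and draws
count-matched negatives for the scorer partitions. The affinity scorer is a
stand-in with the contract "sequence in, score in [0, 1]": a PWM estimated
by anchoring on the most enriched width-w word in the positives and stacking
each positive's closest window to that anchor (stacking several enriched
words directly would mix phase-shifted fragments of one motif), converted to
log-odds against the negative base composition, with a logistic calibration
of the best-window score fitted by ridge-penalized maximum likelihood — the
penalty keeps the fit finite when the classes are linearly separable, where
unpenalized logistic regression diverges and degenerates into a 0/1 step.

The experiment fine-tunes the pre-trained model on the generator partition
(positives only), generates as many sequences as the test partition holds,
scores the generated / positive-test / negative-test groups, and runs the
novelty search of generated sequences against the full positive set. Desk
scale matters here: with a 26k-parameter model, a ~100-sequence fine-tuning
set and tens of epochs (against a 500-epoch original recipe), whether the
sampler reliably emits the implanted motif varies with the run seed; the
fixed-seed acceptance checks in the test suite demonstrate the qualitative
lift (generated affinity above the background mean across three generation
repeats), and single runs at other seeds can land lower.

The ablation compares a scratch-trained model (same architecture, random
initialisation, constant 1e-3, early stopping with patience 3) against the
fine-tuned pre-trained model, generating equal batches and comparing
identical-hit and no-hit percentages. The fixture that makes the comparison
informative is *deliberately redundant*: a handful of distinct motif-bearing
sequences repeated many times. Redundancy is the point — the validation
split then contains copies of the training content, so validation loss
genuinely keeps improving while the scratch model memorizes, early stopping
does not fire prematurely, and the scratch model ends up reproducing
training sequences verbatim while the fine-tuned model, anchored by its
pre-training, generates more novel output. This reproduces the direction of
the original comparison (ablation: far more identical hits, far fewer
no-hits), not its magnitudes.

# What the synthetic corpora do and do not show

The Markov backgrounds emulate local composition structure and length
dispersion; the hairpin corpora guarantee a foldable structure by
construction; the implanted-motif sets make the positive/negative contrast
learnable by a PWM. None of them carry the family structure, conservation
patterns, expression biases or crosslinking artefacts of real RNA corpora
and CLIP data. Green tests therefore certify the machinery — tokenization,
optimisation, decoding, statistics and their oracles — under controlled
conditions; they do not certify biological performance of a model trained at
desk scale on synthetic data.

# Numerical choices and degenerate inputs

- All log-probabilities and NLLs are natural-log; softmaxes are computed
  with max-subtraction; LayerNorm uses eps 1e-5.
- Learning-rate warmup starts at exactly 0; the decay is per-step.
- A non-finite training loss aborts with a diagnostic rather than continuing.
- Sequences of length ≤ k are returned unchanged by the k-let shuffle (the
  class of valid shuffles is a singleton).
- `trainBPE()` on a corpus that cannot support the requested vocabulary
  returns the smaller vocabulary with a warning and `reachedTarget = FALSE`.
- Empty FASTA files read as empty sets; empty generation batches and
  zero-epoch fine-tuning are identities.
- All randomness flows through one seeded generator per call (`seed`
  arguments), with child streams derived by a deterministic string hash; no
  function touches the caller's RNG state.

# Problem sizes used by the checks

The shipped checks use: 300 optimizer steps for the memorization run
(500 copies of one 20-nt sequence; per-token validation NLL reaches
~0.005 nats), a 2,000-sequence corpus for the 1,024-token vocabulary run,
200 random short sequences for the folding-oracle equivalence, 10^4
randomised cases for the shuffle invariant, and 200/200 binding sequences
for the scorer and workflow demonstrations. These sizes were chosen as the
smallest at which each property is stably visible.

# Known limitations

- The built-in fold backend ranks stability by weighted pair counts only; no
  stacking, dangles or temperature dependence.
- The novelty e-value is calibrated empirically on decoys per run; it is a
  per-run significance scale, not a database-portable statistic.
- The trainer is single-threaded CPU R; it is meant for desk-scale
  experiments and teaching-quality transparency, not production training.
- Fine-tuning outcomes at desk scale are seed-sensitive (see the binder
  section).
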