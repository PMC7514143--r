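---
title: "Extracting drug-drug interactions with a recurrent hybrid convolutional network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting drug-drug interactions with a recurrent hybrid convolutional network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddinet)
```

## The task

A drug-drug interaction (DDI) is a combined pharmacological effect of two
co-administered drugs. The extraction task addressed by this package is
sentence-level relation classification: given a sentence that mentions a
pair of drug entities, assign the pair one of five labels — *Mechanism*
(a pharmacokinetic mechanism is described), *Effect* (a pharmacodynamic
effect), *Advice* (a recommendation about co-administration), *Int* (an
interaction is asserted with no further detail) or *Negative* (the sentence
does not assert an interaction for this pair). A sentence with $m$ drug
mentions contributes $\binom{m}{2}$ candidate pairs, which makes the label
distribution extremely skewed towards *Negative*: in the benchmark corpus
format this package targets, negatives outnumber positives roughly 6:1
before filtering.

The package covers the full pipeline: corpus I/O in the DDIExtraction-2013
XML dialect, preprocessing (drug blinding, rule-based negative filtering,
tokenization, fixed-length encoding with position features), the neural
classifier, training with an improved focal loss, micro-averaged
evaluation, a synthetic corpus generator, and a command-line interface.

## Preprocessing

**Drug blinding.** For each candidate pair the two candidate mentions are
replaced by `DRUG1` and `DRUG2` and every other drug mention by `DRUG0`, so
the classifier generalizes over drug names and each instance encodes
exactly one pair. Replacement is offset-based from the largest offset
backwards, so earlier offsets never shift. Discontinuous mentions (offsets
`"a-b;c-d"`) are blinded at their first span and the remaining spans are
deleted; this keeps token alignment simple and matters only for corpus
dialects that use discontinuous annotation.

**Negative-instance filtering.** Pairs that trivially cannot interact are
removed, *only* when labelled Negative, under three explicit rules (each
individually toggleable, every removal logged):

* **R1** — same name after case-folding, or one mention is a parenthesized
  abbreviation immediately following the other (`"acetylsalicylic acid
  (ASA)"`);
* **R2** — coordinate structure: every token strictly between the two
  blinded mentions is one of `, ; and or /` or another `DRUG0` mention;
* **R3** — specialization: one mention's text is a strict substring of the
  other's, or the mentions are linked by "such as" / "including" / "e.g."
  with no other content word between them.

These predicates are this package's operationalization of filtering rules
that the literature describes only informally; the removal log (a TSV of
instance id, rule, mention texts) exists precisely so the filtering
decision trail can be audited against corpus statistics. Positive instances
are never removed: the benchmark statistics show positives nearly unchanged
by filtering, and strict exemption makes the behaviour deterministic and
testable.

**Tokenization and encoding.** The tokenizer splits on whitespace,
separates punctuation into standalone tokens, lowercases everything except
the `DRUG*` symbols and maps every digit to `0` (so `44%` becomes `00 %`).
Instances are encoded to a fixed `max_len` (default 150): shorter sequences
are padded with token id 0, longer ones truncated. If plain head truncation
would drop an entity token, the window is re-centred so both entities
survive whenever their span fits in `max_len`; otherwise the instance is
flagged rather than silently corrupted, because an instance without its
entities is unlabelable. Relative distances of each token to `DRUG1` and
`DRUG2` are clipped to $[-(L{-}1), L{-}1]$ and shifted by $+L$ (with
$L = \texttt{max\_len}$), so a single embedding table of $2L$ rows suffices
and index 0 can be reserved for padding.

## The network

**Semantic embedding with recurrent context.** Each token $w_i$ has a word
embedding $e_w(w_i) \in \mathbb{R}^{n_w}$. Its *left context* $e_l(w_i)$ is
produced by recurrent cells reading the preceding tokens, and its *right
context* $e_r(w_i)$ by cells reading the following tokens; each context is
the concatenation of two directional hidden states of size `hidden`, so
$n_l = n_r = 2\cdot\texttt{hidden}$. The three are concatenated and fused
by a fully connected layer,

$$E_s(w_i) = W_s\,[\,e_l(w_i);\, e_w(w_i);\, e_r(w_i)\,] + b_s,$$

reducing $n_s = n_l + n_w + n_r$ (600 at the defaults) to `n_fused`
dimensions. The reduction matters because the next ingredient, the position
embedding, is small, and a large dimension gap would drown it.

*Design decision (context causality).* The recurrence equations for this
architecture can be read two ways: with the second directional state of the
left context running backwards from the end of the sentence (in which case
it sees future tokens), or as a second independent recurrence over the same
preceding-token input. The first reading contradicts the stated role of the
left context — a summary of what precedes the token — so the default
`context_mode = "causal"` uses two independent causal recurrences over the
shifted input for each side (the property "permuting tokens after position
$i$ never changes the left context at $i$" is tested). A conventional full
bidirectional encoding over the whole sentence is available as
`context_mode = "bilstm"`; it is not causal and exists for ablation. The
cell is an LSTM by default; `cell_type = "rnn"` gives the plain
$h_t = \tanh(W_x x_t + W_h h_{t-1} + b)$ recurrence that the equations
literally describe. Boundary states are zero vectors, the conventional
neutral choice.

*Design decision (where position embeddings attach).* The per-token vector
is $E_i = [E_s(w_i);\, e_{p1}(i);\, e_{p2}(i)]$ of size
$N_E = n_\text{fused} + 2 n_d$: the position embeddings are concatenated
*after* fusion. Attaching them before fusion would feed them through $W_s$
and defeat the stated purpose of keeping position information un-drowned,
so post-fusion concatenation is the default and the pre-fusion variant is
not offered. With the defaults ($n_\text{fused}=200$, $n_d=15$) the
semantic:position ratio is 200:30. `n_fused = 200` itself is a package
choice (the reference setting never states it); it keeps the fused
dimension equal to the word-embedding dimension and is configurable.

**Hybrid convolution.** Two parallel branches read the embedded sentence.
The *typical* branch applies filters over dense windows of $k$ consecutive
tokens,

$$\mathrm{Conv}_i = \mathrm{ReLU}(W_f\,E_{i:i+k-1} + B_f),
\qquad i = 1,\dots,n-k+1,$$

capturing local consecutive context. The *dilated* branch spaces the $k$
taps $d$ positions apart ($E_i, E_{i+d}, \dots, E_{i+(k-1)d}$, output
length $n-(k-1)d$, receptive span $(k-1)d+1$), capturing dependencies
between separated words — coordination, anaphora — without extra
parameters. With $d = 1$ the dilated operation reduces exactly to the
typical one, which the tests exploit as an oracle. Both branches use filter
sizes 3 and 5 by default, dilation 2.

*Design decision (stacking and pooling).* Each (branch, filter size) tower
applies two convolution blocks, each followed by stride-$w$ max pooling
(window $w = 2$), then a global max pool over the remaining positions; the
four pooled vectors are concatenated into the sentence vector $s$. A
sliding max alone would leave a variable-length sequence, but the softmax
layer needs a fixed-size input, so the final global pool is forced; the
stride-$w$ intermediate pooling is the package's reading of "convolutions
followed by a max pooling layer" as (conv → pool) blocks. Layer 1 uses
valid windows — so the output-length formulas above hold exactly and are
testable — while layer 2 uses same-padding, so that short sentences survive
two reductions. A trailing partial pooling window is pooled as-is rather
than dropped.

**Output.** Dropout (probability 0.5, training only, inverted scaling) is
applied to $s$, followed by an affine map and softmax over the five
classes.

## Loss and training

With $p_t$ the predicted probability of the instance's true class, the
training objective blends the $\alpha$-weighted focal loss with plain
cross-entropy:

$$L = -\,e\,\alpha_t\,(1-p_t)^\gamma \log p_t \;-\; (1-e)\,\log p_t,$$

with $\gamma = 2$ and $e = 0.9$ by default. The modulation $(1-p_t)^\gamma$
down-weights easy instances — at $p_t = 0.9$, $\gamma = 2$ the focal term
is exactly 100 times below cross-entropy — so gradient is spent on hard
ones, and the per-class weight

$$\alpha_i = \frac{1/\mathrm{Count}_i}{\sum_j 1/\mathrm{Count}_j}$$

(inverse class frequency, computed once from the *post-filtering* training
counts) rebalances the skewed label distribution. On the benchmark filtered
training counts (822/1669/1319/188/19012) this gives weights rounding to
0.15/0.08/0.10/0.67/0.01. The $e$-weighted cross-entropy term acts as a
regularizer against over-fitting to the reweighting. The rendering of the
blend in the source material is ambiguous; it is read as $-(1-e)\log p_t$,
the only reading under which $e \in [0,1]$ interpolates between the two
losses (at $e=0$ the loss is exactly cross-entropy, which is tested to
machine precision).

Numerical choices: $p_t$ is floored at $10^{-7}$ before the logarithm;
batch losses are reduced by the mean (so the learning rate does not scale
with batch size); optimization is Adam at learning rate $10^{-3}$ (the
reference setting names the optimizer but not the rate; $10^{-3}$ is its
canonical default and configurable); batch size 32. Epochs are capped at 50
with early stopping (patience 5) on dev micro-F, since no schedule is
stated and early stopping matches the loss design's stated concern with
over-fitting. Weight matrices use Glorot-uniform initialization, embedding
tables uniform $[-0.05, 0.05]$ (also the initialization for
out-of-vocabulary tokens when pretrained word2vec-format vectors are
supplied), and LSTM forget gates start at bias 1. Training is deterministic
given the seed. The backpropagation through the full architecture is
verified against central-difference numerical gradients to a relative error
below $10^{-4}$ in every cell/context/fusion mode.

## Evaluation

The task metric is micro-averaged precision/recall/F pooled over the four
*positive* classes: TP is the positive-class diagonal of the 5×5 confusion
matrix, FP the off-diagonal mass in positive columns, FN the off-diagonal
mass in positive rows; the Negative class contributes only through its
confusions with positive classes. This exclusion is forced by arithmetic on
the published worked example this package reproduces (722/934 = 77.30%
precision and 722/979 = 73.75% recall only hold when Negative is excluded
from pooling) and is the standard convention of the task. `micro_prf()` is
tested for exact agreement with an independent brute-force count over raw
label vectors; `error_breakdown()` decomposes the off-diagonal mass into
positive→Negative, Negative→positive and positive↔positive confusions.
Percentages are displayed with round-half-up at two decimals; one published
per-type value (Effect F) appears to be truncated rather than rounded, so
worked-example tests compare per-type F at ±0.01.

## The synthetic corpus generator

`generate_ddi_corpus()` emulates the *structure* of the task so every
module is testable without the licensed benchmark download: five-class
labels with configurable proportions (defaulting to the filtered benchmark
training distribution, ~1:4.8 positives:negatives), invented drug names
(pairwise substring-free, so rule R3 never fires by accident), exact
character offsets, at least two mentions per sentence, optional distractor
mentions that create genuinely negative extra pairs, and XML that
round-trips byte-identically under a fixed seed.

The class signal is carried by per-class trigger phrases ("should not be
coadministered with", "may potentiate the effect of", "increases the plasma
concentration of", "may interact with"), which makes the task nearly
separable by design: end-to-end tests must be fast and stable, and a
trigger-phrase task is sufficient to exercise learning, imbalance handling
and evaluation. A `hard_mode` flag overlaps the Int and Effect trigger
vocabulary to mimic the Int→Effect confusion observed on real data. What
passing these tests shows is that the implementation learns and evaluates
correctly — not that it reaches benchmark accuracy on real biomedical
language, whose vocabulary, syntax and annotation noise the generator makes
no attempt to match.

## Problem sizes used by the test suite

The shipped tests train at deliberately small scale so the whole suite runs
in minutes on one CPU: the end-to-end smoke test uses 2,000 generated
training sentences, a 500-sentence held-out split and a reduced network
(24-dimensional word embeddings, 8 hidden units, 32 fused dimensions, 8
filters, `max_len` 30, 10 epochs) and checks held-out micro-F ≥ 0.80; the
focal-vs-cross-entropy comparison uses five paired seeds on a 1:19
imbalanced corpus of 700 training / 300 test sentences and 6 training
epochs — a budget at which plain cross-entropy has typically not yet
recovered the minority classes, which is precisely the regime the
reweighted loss is for; gradient checks run on a miniature configuration
where central differences are affordable. These sizes are the package's
choices for its own verification, not statements about the scale the
implementation supports.

## Known limitations

* The headline benchmark figure of the original method requires the
  licensed DDIExtraction-2013 corpus and long training runs; it is out of
  scope here. The evaluator reproduces the published worked numbers from
  the published confusion matrix, and the learning machinery is verified on
  synthetic data and by gradient checking.
* The exact 22 positive training instances that the original filtering
  removed cannot be reconstructed from published information; the strict
  positive-exemption rule here will not reproduce that delta.
* Cross-sentence and nested mentions are treated as malformed input (the
  target corpus dialect has neither in practice).
* Training is pure R on one core; it is adequate for the synthetic scales
  above, and the architecture dimensions are fully configurable, but no
  GPU or multicore path is provided.
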