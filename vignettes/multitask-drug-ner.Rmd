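---
title: "Joint drug-name recognition and normalization: model and design notes"
author: "drugner"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint drug-name recognition and normalization: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drugner)
```

## The problem

Drug-named entity recognition (DNER) locates drug mentions in text and types
them (Drug, Brand, Group, Drug_n in the drug–drug-interaction challenge
corpora); drug-named entity normalization (DNEN) maps each mention to an
identifier in a controlled vocabulary. The two tasks are mutually informative:
a B-DRUG tag tells the normalizer where to look, and a confident normalization
ID tells the recognizer what type the span must have. `drugner` implements
both as per-token sequence labeling over a shared encoder, with explicit
cross-task feedback, and trains them jointly by asynchronous task sampling.

## Model

**Token representation.** Three concatenated channels, in fixed order:

1. *Word embeddings* (default width 100), either loaded from a plain-text
   vector file or initialized uniformly on $[-\sqrt{3/d}, +\sqrt{3/d}]$.
2. *Character CNN* (default width 30): character embeddings of width 30,
   convolved with 30 filters of window 3 and max-pooled over time, so that
   prefix/suffix/stem cues shared between drug names (e.g. *amidopyrine* /
   *aminopyrine*) are available to the tagger. Dropout (rate 0.5) is applied
   to the character embeddings during training only.
3. *Contextual vectors* (optional): a small bidirectional language model is
   run over the sentence and its $L{+}1$ layer representations are combined
   with softmax-normalized trainable weights,
   $\mathrm{ctx}_k = \sum_{j=0}^{L} w_j h_{k,j}$. Layer 0 is the
   context-independent input embedding duplicated to the common width; layer
   $j$ concatenates the forward state (conditioning on positions $\le k$) and
   the backward state (conditioning on positions $\ge k$). The combination is
   implemented exactly as the normalized weighted sum, with an optional scalar
   gain defaulting to 1. The biLM can be pretrained at toy scale by two-way
   next-token prediction (`train_bilm`), or the channel can be fed from
   precomputed vectors.

**Shared encoder.** A bidirectional LSTM (default state size 200, zero initial
states) over the token representations; position $t$ is represented by
$v_t = (\overrightarrow{h}_t, \overleftarrow{h}_t)$.

Two LSTM cells are provided behind `variant`. The `"cifg"` cell is the
coupled input–forget peephole form,

$$i_t = \sigma(W_{xi}x_t + W_{hi}h_{t-1} + W_{ci} \circ c_{t-1} + b_i),\quad
c_t = (1-i_t)\circ c_{t-1} + i_t \circ \tanh(W_{xc}x_t + W_{hc}h_{t-1} + b_c),$$
$$o_t = \sigma(W_{xo}x_t + W_{ho}h_{t-1} + W_{co} \circ c_t + b_o),\quad
h_t = o_t \circ \tanh(c_t),$$

while `"standard"` is the conventional cell with an independent forget gate
and no peepholes. Both formulations appear in the BiLSTM-CRF lineage this
model belongs to; the default hyperparameter set assumes no peepholes, so
training uses `"standard"`, and `"cifg"` is kept for unit-level fidelity
checks and experimentation. Gradient support covers the training variant.

**Recognition head (CRF).** Per-token emissions $P \in \mathbb{R}^{n\times k}$
feed a linear-chain CRF with transition matrix $A$ of size $k{+}2$ (explicit
START/STOP). The sequence score is
$s(z) = A_{START,z_1} + \sum_i A_{z_i,z_{i+1}} + A_{z_n,STOP} + \sum_i P_{i,z_i}$,
the loss is the exact negative log-likelihood
$\log Z - s(z^{gold})$ computed by the forward recursion in log space, and
decoding is Viterbi. Start/stop transitions are learned. A hard BIO transition
mask (forbidding, e.g., I-BRAND directly after B-DRUG) is available but off by
default: the CRF is normally left to learn the schema, as the emissions and
transitions suffice in practice.

**Normalization head.** Per-token softmax over the normalization vocabulary
(including a reserved NIL for non-entity tokens). A CRF is deliberately not
the default here: the controlled vocabulary is large and its transition
statistics are data-starved.

**Explicit feedback.** The head input for one task augments the shared vector
with the other task's predicted labels mapped into the representation space:
$v^{DNER}_i = v_i \circ (v_i + y^{DNEN}_i U)$ and
$v^{DNEN}_i = v_i \circ (v_i + y^{DNER}_i V)$, where $U$ and $V$ are trainable
mapping matrices initialized at zero ($U$: DNEN to DNER, $V$: DNER to DNEN).
We concatenate the uncorrected vector alongside the corrected one
(`feedback_mode = "concat"`) so the head never loses the raw representation;
a corrected-only variant ($v_i + yM$ alone) is available behind a flag.
During training the feedback labels are the current model's own first-pass
(feedback-free) softmax distributions, gradient-stopped — gold labels of the
other task are not assumed to exist for the sampled instance; at inference
the predicted one-hot is used.

**Asynchronous multitask training.** Each step samples a task (by default
proportionally to dataset sizes), draws the next minibatch of that task's
data, and updates the shared encoder plus that task's head and feedback
matrix. One epoch draws as many instances in expectation as the scheduled
datasets contain. Single-task training is exactly the same loop with a
degenerate schedule, which makes ablations step-for-step comparable — with
feedback off and a degenerate schedule, multitask training reproduces
single-task training exactly.

## Hyperparameters

| name | default | meaning |
|---|---|---|
| `window_size` | 3 | char-CNN window (characters) |
| `num_filters` | 30 | char-CNN filters = char channel width |
| `state_size` | 200 | LSTM state per direction |
| `dropout_rate` | 0.5 | dropout on character embeddings (training) |
| `batch_size` | 10 | sentences per update |
| `initial_lr` | 0.015 | SGD learning rate at epoch 0 |
| `decay_rate` | 0.05 | lr$_e$ = lr$_0/(1 + 0.05\,e)$ |
| `gradient_clip` | 5.0 | global L2 gradient-norm bound |
| `word_dim` / `char_dim` / `elmo_dim` | 100 / 30 / 1024 | channel widths |

The word and character widths default to 100 and 30 — the character width
matching the 30-filter character CNN and its initialization convention — and
both pairings are configurable. Embedding tables are initialized uniformly on
$\pm\sqrt{3/dim}$, the variance-preserving bound conventional in this model
family ($\approx 0.316$ at dim 30); a literal $\pm 3/dim$ bound, the other
common convention, is available through the `bound` arguments. SGD with the
decayed schedule is the default optimizer; AdaGrad, Adadelta, RMSProp and
Adam are provided for comparison runs.

## The synthetic corpus

Real drug corpora are licensed, so every experiment in the package runs on a
generator with known ground truth (`synthetic_spec`, `generate_corpus`).
Sentences are drawn over a closed context vocabulary; entity surface forms
(1–2 tokens) are attached to normalization IDs with controllable synonymy,
entity starts are sampled per slot (default rate 0.2), and the four entity
types follow the 2013-challenge proportions (Drug 63%, Brand 10%, Group 23%,
Drug_n 4%). Two regimes matter:

* **Separable** (default): entity words are disjoint from the context
  vocabulary, so a correct implementation must reach near-perfect F1 — this is
  the training-convergence fixture.
* **Correlated**: the normalization ID is a deterministic function of
  (surface form, type), and a small fraction of context tokens (default 5%)
  are homographs of entity words. This is the regime where the two labelings
  carry mutual information and cross-task feedback can help. The homograph
  rate was chosen for realism: most drug mentions in real corpora are
  unambiguous, and at much higher rates the per-token Bayes error dominates
  every model, leaving nothing for a comparison to measure.

What the generator does **not** emulate: real morphology and drug
nomenclature, document structure, nested/overlapping mentions, and
class-dependent context. Passing tests therefore demonstrate correctness of
the machinery and the direction of the multitask effect, not clinical-grade
accuracy.

## Problem sizes used by the test suite

All chosen as the package's own desk-scale experimental design:

* Convergence: 2,000 separable sentences, state size 50, otherwise default
  hyperparameters, at most 10 epochs (early-stopped at strict F1 0.95).
* Multitask comparison: 400 correlated sentences, state size 30, word width
  50, 30 epochs, five seeds. The single-task arm plateaus by roughly epoch
  12; the multitask arm needs ~20+ epochs before the normalization head is
  good enough for its supervision and feedback to pay off, so the comparison
  is read at 30 epochs.
* Exact-inference checks enumerate all $k^n$ paths for $n \le 6$, $k \le 5$.

The convergence fixtures use the word and character channels; the separable
corpus is decidable from word identity alone, so the contextual channel is
exercised by its own unit tests (directionality, mixing, pretraining loss)
rather than by the convergence runs.

## Numerical choices and degenerate inputs

* All CRF path arithmetic is in log space; forbidden transitions carry a
  $-10^4$ sentinel instead of $-\infty$ so gradients stay finite.
* Viterbi ties break toward the lowest label index at the latest decision
  point; normalization argmax ties likewise.
* Batch loss is the mean per-sentence loss (CRF NLL for recognition, summed
  token cross-entropy for normalization), keeping the learning-rate scale
  independent of batch size.
* Ill-formed BIO sequences are repaired by promoting stray I-X to B-X —
  conservative, keeps recall measurable; decoded output is always re-checked
  against the schema.
* Corpus character offsets are 0-based inclusive (the DDI convention);
  entity offsets force token splits so spans always align with token
  boundaries. Discontinuous (semicolon-separated) offsets annotate each
  fragment independently. Overlapping entities are rejected.
* One-character words are handled by symmetric zero padding in the char-CNN;
  caller-side padding characters are inert. The padding row of every
  embedding table is frozen at zero.
* A single run seed fans out to independent derived streams (corpus
  generation, initialization, shuffling/dropout/task sampling), so any one
  component can change its consumption pattern without perturbing the others,
  and every run is exactly reproducible.

## Known limitations

* No nested or overlapping mentions; no sentence splitting of raw documents.
* The normalization vocabulary is closed at training time; unseen IDs cannot
  be predicted.
* Training is pure R on one core: fine at desk scale (thousands of short
  sentences), not intended for full-corpus GPU-scale runs.
* The "paper"-variant cell is forward-only; training always uses the
  standard cell.

## A minimal run

```{r example, eval = FALSE}
spec <- synthetic_spec(n_sentences = 400, seed = 1)
corpus <- generate_corpus(spec)
alphabets <- build_alphabets(corpus)
cfg <- run_config(state_size = 30, word_dim = 50, task = "multitask",
                  epochs = 10, seed = 1)
model <- init_model(alphabets, cfg)
fit <- multitask_train(model, corpus, corpus)
pred <- predict_corpus(corpus, fit$model)
evaluate_corpus(corpus, pred, "strict")
```
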