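---
title: "Methods: order-sensitive neural risk prediction from SOEP notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: order-sensitive neural risk prediction from SOEP notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

General-practice records hold years of free-text consultation notes per
patient, written in the Dutch SOEP structure (Subjective, Objective,
Evaluation, Plan). For a rare outcome such as lung cancer (prevalence around
0.4% in an over-30 primary-care population), predictive signal is scattered
across many visits and is ordered in time: what matters is not only which
complaints appear but when, and in what sequence. `hanrisk` implements an
order-sensitive neural pipeline for this setting — from cohort construction
through model fitting to a bootstrap evaluation protocol — together with a
synthetic corpus generator, so that every stage is testable without access to
any real patient data.

## Model

Each patient is one *document*: one sentence per GP visit, in date order. A
sentence is the concatenation of the four SOEP fields, with the literal
marker tokens `S`, `O`, `E`, `P` kept as ordinary words. Tokens are mapped to
frozen static embeddings (below).

The core architecture is a hierarchical attention network:

* **Word level.** A bidirectional LSTM encodes the words of each sentence;
  forward and backward states are concatenated, `h_t = [f_t ; b_t]`.
  Additive attention pools them: `u_t = tanh(W h_t + b)`,
  `alpha_t = softmax(u_t . v)` over real (unmasked) positions, sentence
  vector `s = sum_t alpha_t h_t`.
* **Sentence level.** A second BiLSTM runs over the sentence vectors in
  visit order, with the same attention scheme producing the document vector.
  The per-visit recurrent states `h_i` are retained.
* **Output heads.** The final risk is `sigmoid(w . z + c)` where `z` is the
  document vector (`han_text`) or the document vector concatenated with
  `relu(W_s x + b_s)` applied to the structured predictor vector `x`
  (`han_combined`, late fusion by concatenation). A shared affine+sigmoid
  head on each sentence-level state yields a per-visit probability `p_i`.

**Target replication.** The training objective replicates the outcome at
every visit:

    L = (1 - lambda) * l(p_final, y) + (lambda / T) * sum_{i=1..T} l(p_i, y)

with `l` binary cross-entropy and `lambda` in [0, 1] (default 0.5, grid
{0, 0.25, 0.5, 0.75, 1} in `tune_grid()`). At `lambda = 0` the loss reduces
exactly to the final cross-entropy. Intermediate supervision shortens the
gradient path to early visits and markedly speeds learning on long
histories.

**Structured predictors** (13 by default): age at the index date, sex, and
window-restricted counts of eleven ICPC codes linked to lung cancer (A04,
B80, B82, P17, R02, R05, R24, R95, T03, T08, L04). The vector length is
configurable (`n_struct`) because the upstream predictor count is not fully
enumerable from the available description; 13 is what the code list, age and
sex add up to.

### Ablation architectures

| kind | hierarchical | attention | replication | notes |
|------|:---:|:---:|:---:|-------|
| `han_text` / `han_combined` | yes | yes | yes | reference models |
| `hn`   | yes | no | yes | attention replaced by masked mean pooling |
| `lstm` | no  | no | yes | word BiLSTM per sentence, patient vector = unweighted mean of sentence vectors |
| `psgnn`| no  | no | no  | sliding 3-word phrases -> hidden layer -> mean -> logistic output |
| `cnn`  | yes | no | yes | two 1-D convolutions over the concatenated word stream, max pooling, per-visit heads |

`model_features()` recovers this table by introspecting which parameter
groups a built network contains. The phrase network represents a 3-word
phrase by concatenating the three static unigram embeddings
(order-preserving); a full phrase-skip-gram would learn phrase vectors
jointly, which is out of scope here.

All forward passes and their hand-written backward passes live in plain R;
no deep-learning framework is used. Gradients of every architecture are
checked against central finite differences (relative error below 1e-4) in
the test suite. Masked positions are pass-throughs of the recurrent state,
so appending padding never changes an output (exact invariance, asserted to
1e-6).

## Cohort preparation

* **Inclusion.** Patients strictly older than 30 years at the index date;
  cases must additionally have at least one note before diagnosis and a
  first visit at least 5 months before diagnosis.
* **Index date.** Diagnosis date for cases, last GP visit for controls — the
  only dates the design anchors windows to. Age is computed at the index
  date.
* **Observation windows.** Cases keep visits in [diagnosis - 29 months,
  diagnosis - 5 months]; controls the same two-year span ending one month
  before their last visit. Months are fixed 30-day intervals: window
  arithmetic stays deterministic and calendar-free. Patients with no
  in-window visit are dropped. The 5-month blind gap is the design's
  early-warning margin: no token dated later than diagnosis minus 5 months
  can reach a case document (asserted as a leakage test).
* **Length exclusion.** Documents whose total word count exceeds the
  empirical 99.7th percentile (the 3-sigma convention) of per-patient counts
  are removed, recomputed per corpus. The alternative reading of a 3-sigma
  rule — a fraction of a fixed hardware memory cap — would tie the cohort to
  a particular machine; the percentile reading is implemented and the
  quantile is configurable.
* **ICPC counts** are restricted to the same observation window — the
  conservative choice (whole-history counting would let a long pre-window
  record leak into the predictors), and the one the generator emulates.
* **Split.** Outcome-stratified 60/20/20 train/tune/test by patient,
  reproducible from a seed. With both classes present, at least three cases
  are required so each fold can hold one.
* **Tokenization** (for ingesting raw text): lowercase, split on
  whitespace, strip leading/trailing punctuation, keep internal hyphens —
  the simplest scheme consistent with unigram embeddings.

## Embeddings

Static unigram skip-gram with negative sampling (5 negatives, noise
distribution proportional to frequency^0.75), trained **only on the
training-fold sentences**; the vocabulary therefore cannot contain a token
private to the tuning or testing folds (asserted). The variant choice
(skip-gram rather than CBOW) follows the more common practice for small
corpora. Defaults: `dim = 100`, `window = 5`, `min_count = 5`,
`epochs = 5`, initial learning rate 0.025 with linear decay, frequent-word
subsampling at t = 1e-3. Updates are applied in chunks of 64 (center,
context) pairs; a chunk this small approximates sequential per-pair SGD,
whereas large aggregated chunks either cancel the structure-bearing update
components (when averaged) or blow up on frequent tokens (when summed).

Two practical points matter on small corpora:

* **Anisotropy.** Skip-gram vectors concentrate along a few global
  directions; on synthetic text the effect is extreme because the background
  text is exchangeable and a degenerate low-rank solution is essentially
  optimal. The vectors are therefore post-processed in the all-but-the-top
  style: subtract the mean vector, remove the top 3 principal components,
  and L2-normalize rows. This restores the near-orthogonality that the
  downstream recurrent encoders need to tell tokens apart, while leaving
  enough of the spectrum for co-occurrence structure (the test suite checks
  that tokens which always co-occur end up with higher cosine similarity
  than tokens which never do).
* **Out-of-vocabulary tokens** map to an all-zeros UNK vector — they
  contribute nothing to the recurrent input and are never an error.

Embeddings are frozen downstream: no gradient reaches the matrix during
model training.

## Synthetic corpus generator

The generator emulates a realistic primary-care study population, not any
real dataset:

* rare outcome (`prevalence` default 0.0039) drawn i.i.d.;
* case/control age shift: normal age-at-index with medians 68 vs 52 years
  (SDs 11.1 and 17.8, recovered from the reported interquartile ranges);
* visit counts negative-binomial (mean 10, dispersion 4) over a 36-month
  span before the index date, dates uniform;
* per-field word counts Poisson (mean 5) over a Zipf-distributed
  (exponent 1.05) synthetic pseudo-Dutch vocabulary, so embedding training
  sees heavy-tailed frequencies without any real PHI;
* per-code ICPC event counts Poisson, case-elevated (0.8 vs 0.3 per code);
* planted signal tokens emitted per sentence with probability
  `signal_rate_case` (default 0.35) inside the case observation window and
  `signal_rate_control` (default 0.05) elsewhere, landing preferentially in
  the S and E fields — mimicking symptom mentions without claiming fidelity
  to real notes;
* sex Bernoulli(0.5) in both classes (no sex breakdown is available to
  emulate).

With `signal_rate_case = 1` and `signal_rate_control = 0` the corpus is
Bayes-separable after windowing: every case sentence carries signal, no
control sentence does. This dial is what the signal-recovery test uses.

What the generator does **not** emulate: real Dutch morphology and syntax,
dependence between text and the coded events, GP coding practice,
non-stationary visit patterns, or any distributional detail of real notes
beyond the published summary counts. Passing tests on this corpus
demonstrate that the pipeline's machinery is correct and can recover planted
structure; they say nothing about predictive performance on real records.
In particular the background text is exchangeable, so the learned
embeddings carry little semantic structure — which is exactly why the
anisotropy correction above is load-bearing.

## Training

Mini-batch Adam (lr 1e-3 by default, batch 32, beta 0.9/0.999), global
gradient-norm clipping at 5, up to 50 epochs with early stopping after 5
epochs without tuning-AUROC improvement; the best-epoch parameters are
retained. The output and visit-head biases are initialised at the log-odds
of the training prevalence, so the first epochs work on discrimination
rather than on finding the base rate — with a 0.4% outcome the base-rate
plateau otherwise dominates early training. No class reweighting or
resampling is applied: the models train at natural prevalence. Everything
(initialisation, shuffling, dropout) is reproducible from seeds, and two
fits with the same seed are bit-identical. `tune_grid()` evaluates an
exhaustive grid on the tuning fold only (the signature takes no test data);
ties break toward smaller `lambda_rep`, then smaller `word_hidden`.

## Evaluation protocol

* **AUROC**: the Mann-Whitney pair statistic (ties count one half).
* **AUPRC**: average precision over descending unique thresholds (step
  interpolation). Trapezoidal PR interpolation is deliberately avoided — it
  is known to over-estimate — so values can differ slightly from tools that
  interpolate.
* **Brier**: mean squared error of the probabilities; reports render it
  x100, following the conventional table format.
* **Threshold metrics** at an inclusive cut-off `p >= 0.004` (the
  prevalence-matched default): sensitivity, specificity, PPV, NPV; a rate
  with an empty denominator is reported as undefined (`NA`), never 0.
  `round(1/PPV)` is the number of high-risk patients needing further testing
  per detected case.
* **Calibration**: LOWESS (span 2/3, no robustness iterations — the
  reweighting would treat the rare positive outcomes as outliers) of the
  outcome on the predicted probabilities, restricted to p at or below a 30%
  trim, where the mass of a rare-outcome model lives. The ideal curve is the
  diagonal.
* **Uncertainty**: percentile bootstrap, 1000 resamples of (label,
  probability) pairs, 2.5th/97.5th percentiles. Resamples that lose a class
  are redrawn — a necessary addition for rank metrics under rare outcomes;
  resampling is not outcome-stratified beyond that.
* **Model comparison**: paired bootstrap — the same resampled patients are
  scored under both models, and the difference is significant (two-sided
  p < 0.05) when 0 falls outside the central 95% interval of the
  differences.

## Problem sizes

Desk-scale sizes keep the full suite and the end-to-end experiment
tractable on one CPU core: the signal-recovery check trains on a 2000-patient
separable corpus at case-rich prevalence 0.2 (embed dim 32, hidden width 16,
learning rate 0.01, batch 16, at most 10 epochs) — at the natural 0.4%
prevalence a 2000-patient corpus would hold too few cases to train on or to
rank; the reference experiment in `scripts/acceptance.R` uses 6000 patients
at 2% prevalence (so the test fold holds about 20 cases — mirroring, at desk
scale, the small-test-fold caveat inherent to rare-outcome evaluation), two
models, 8 training
epochs and 1000 bootstrap resamples. At those conditions the text-only model
sits at the edge of learnability — 72 training cases carrying a moderate
per-sentence signal are barely enough for a recurrent encoder — while the
combined model succeeds through its structured branch; the asymmetry is
itself a faithful desk-scale illustration of why structured predictors are
fused in. The pipeline defaults (`experiment_config()`) describe a larger
20000-patient experiment at natural prevalence for users with more time.

## Known limitations

* The generator's free parameters (signal rates, text lengths) are knobs,
  not estimates of any real corpus; conclusions transfer to real data only
  insofar as the planted-signal abstraction holds.
* Training is pure R: correct and reproducible, but not fast; the intended
  scale is tens of thousands of synthetic patients, not the hundreds of
  thousands of a production EHR extraction.
* With prevalence 0.4% at desk scale, a test fold holds a handful of cases;
  rank metrics computed there are honest but wide — the acceptance
  experiment raises prevalence to 2% for that reason and says so.
* The per-visit replication head for the CNN ablation pools within each
  visit's word span, matching the recurrent models' replication scheme;
  per-window replication is a plausible alternative not implemented.
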