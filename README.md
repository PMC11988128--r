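# hanrisk

Order-sensitive neural risk prediction from longitudinal primary-care notes,
for a rare outcome (early lung cancer), in pure R.

General practitioners' free-text consultation notes — written in the Dutch
SOEP structure (Subjective, Objective, Evaluation, Plan) — hold predictive
signal that structured codes miss, and that signal is *ordered*: which
complaints appear, in which visits, in which sequence. `hanrisk` is for
biostatisticians and clinical-ML researchers who want a fully inspectable,
dependency-light implementation of this modelling pipeline: a hierarchical
attention network over words and visits, trained with a target-replication
objective, optionally fused with structured predictors, and evaluated with
the bootstrap protocol appropriate for rare outcomes. Because real GP
records are private, the package ships a synthetic SOEP-corpus generator
with planted, windowed signal, so every stage is testable end to end.

## The model

Each patient is a document: one sentence per visit (date order), each
sentence the four SOEP fields with literal `S O E P` marker tokens. Words
map to frozen skip-gram embeddings trained on the training fold only.

A word-level BiLSTM with additive attention (`u_t = tanh(W h_t + b)`,
`alpha = softmax(u_t . v)`, `s = sum_t alpha_t h_t`) encodes each sentence; a
sentence-level BiLSTM with the same attention scheme produces the document
vector and per-visit states `h_i`. The risk is `sigmoid(w.z + c)` with `z`
the document vector (HAN-Text) or its concatenation with a ReLU layer over
the 13 structured predictors — age, sex and eleven ICPC code counts
(HAN-Combined, late fusion). Training minimises the target-replication loss

    L = (1 - lambda) * l(p_final, y) + (lambda / T) * sum_i l(p_i, y)

where `l` is binary cross-entropy and `p_i = sigmoid(w_v . h_i + c_v)` is a
per-visit probability: the outcome is replicated at every intermediate
visit, weighted by `lambda`. Four ablations are included (hierarchy without
attention, flat BiLSTM, phrase-skip-gram network, two-layer CNN); see the
methods vignette (`vignettes/han-risk-methods.Rmd`) for every modelling
decision. All forward and backward passes are hand-written, vectorised base
R, with gradients verified against finite differences in the tests.

## Worked example

One seeded call runs the whole experiment — simulate, window the cohort,
train fold-restricted embeddings, fit, evaluate on the held-out fold:

```r
library(hanrisk)

cfg <- experiment_config(
  generator = list(n_patients = 1200L, prevalence = 0.1,
                   signal_rate_case = 1, signal_rate_control = 0.02,
                   visits_per_patient = c(mean = 6, dispersion = 4),
                   words_per_field = c(mean = 4)),
  embedding = list(dim = 24L, window = 2L, min_count = 2L, epochs = 2L),
  models = list(han_text = list(word_hidden = 12L, sent_hidden = 12L,
                                attn_dim = 24L)),
  training = list(epochs = 6L, batch_size = 16L, lr = 0.01),
  evaluation = list(cutoff = 0.1, n_boot = 500L),
  seed = 42L)

bundle <- run_experiment(cfg)
print(bundle$models$han_text$report)
#> n=195, cutoff=0.1, 500 bootstrap samples
#>   AUROC: 0.9934 (0.9792, 1.0000)
#>   AUPRC: 0.9752 (0.9305, 1.0000)
#>   Brier (x100): 1.419 (0.318, 2.826)
#>   sensitivity: 0.9615 (0.8739, 1.0000)
#>   specificity: 0.9822 (0.9585, 1.0000)
#>   ppv: 0.8929 (0.7632, 1.0000)
#>   npv: 0.9940 (0.9791, 1.0000)
```

Reading the numbers: this corpus plants a signal token in every in-window
case sentence (`signal_rate_case = 1`) and almost never in controls, so a
correct pipeline should approach perfect discrimination — the held-out
AUROC of 0.993 (195 test patients, percentile-bootstrap interval in
parentheses) says the network recovered the planted signal from text alone.
The Brier score is rendered x100 by convention; at the prevalence-matched
cut-off 0.1, sensitivity/specificity/PPV/NPV come from the test-fold
confusion matrix. `make_report(bundle, "results/")` writes the same numbers
as JSON and CSV tables, plus per-model predictions and calibration-curve
points.

Lower-level entry points: `generate_corpus()`, `prepare_cohort()`,
`train_embeddings()`, `han_fit()` (returns an object with `print`,
`summary`, `coef`, `predict`, `plot` methods), `metric_report()`,
`bootstrap_diff_test()`. A thin CLI over the same functions is in
`inst/cli/hanrisk.R` with subcommands `simulate / prepare /
train-embeddings / train / evaluate / compare / run`.

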