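---
title: "Auditing the accuracy and reliability of report classifiers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing the accuracy and reliability of report classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xaudit)
```

## The problem

Hospitals accumulate free-text reports whose *purpose* is valuable
structured information: an MRI report on a multiple-sclerosis patient is
written for initial **Diagnosis** (class 1), for assessing disease
**Progression** or medication effect (class 2), or for **Monitoring**
secondary complications such as PML (class 3). A classifier that extracts
this label enables patient-flow quantification, but only if it is
trustworthy — accurate *and* relying on clinically meaningful vocabulary
rather than spurious regularities. `xaudit` implements that two-sided
audit as a reusable, fully seeded pipeline.

## The synthetic study population

Real reports cannot be shipped, so the generator
(`generator_config()` / `generate_corpus()`) emulates the structural
properties the audit exercises. Its defaults are fixed once and define the
package's study conditions:

| parameter | default | rationale |
|---|---|---|
| `n_per_class` | 271 / 531 / 21 | strongly imbalanced three-class mix typical of retrospective MRI-report collections; `n_total` apportions this ratio at any scale by largest remainder |
| `report_length_range` | 20–60 tokens | radiology reports are short; the length distribution of the emulated data is unknown, so a moderate uniform range is a free parameter chosen once |
| `n_valid_per_class` | 5 | matches the top-5 explanation budget, so a perfect explainer can in principle fill its list with class evidence |
| `n_perhaps_per_class` | 3 | context-dependent vocabulary exists but is rarer than definitive vocabulary |
| `n_wrong`, `n_filler` | 5, 60 | a handful of globally spurious words (the "MRI" effect) over a larger neutral background |
| `p_valid_inject` | 0.7 | class words are typical but not certain, so classification is learnable yet not trivial |
| `p_perhaps_inject` | 0.5 own class, 0.125 other classes | "validity depends on context" is operationalized as an elevated own-class rate versus a reduced other-class rate, without modeling context itself |
| `p_wrong_inject` | 0.8 | spurious words appear in most reports *independently of the label*, the defining property of a spurious feature |
| `p_misspell` | 0.1 | time-pressed clinical writing produces corrupted surface forms; each corruption is a deterministic single-character deletion recorded in the lexicon's `normalization_map` |

The token inventory is deliberately synthetic (pseudo-words with role
prefixes) because every audit statistic depends on word *roles*, not on
language identity; real vocabularies enter through `domain_lexicon()`
files. What the generator does **not** emulate: syntax and discourse
structure, negation, correlated symptom clusters, section headers, and
annotator noise. Passing audits on this corpus therefore demonstrate that
the machinery is correct and discriminating — not that any particular
clinical model is reliable on real data.

## Preprocessing

`preprocess_text()` applies, in a fixed order: newline removal,
tokenization on whitespace/punctuation boundaries (hyphens split tokens,
since all punctuation is removed anyway), lowercasing, lemmatization,
removal of digit-bearing tokens, of single-character tokens, and of
stopwords. Lowercasing precedes lemmatization so the hook always sees
canonical case. The lemmatizer defaults to the identity — lemmatization
quality in non-English clinical text is poor and its failures (e.g. the
abbreviation "afwk" passing through unchanged) are tolerated downstream,
where the alignment stage's normalization map plays the role of manual
correction. Running stopword removal last guarantees the output invariant
(lowercase, length ≥ 2, no digits or punctuation, no stopwords) and makes
the pipeline idempotent. A Dutch stopword list is bundled as the default;
any one-word-per-line file can replace it.

## Classification and evaluation

Features are TF-IDF with the de-facto standard smoothed inverse document
frequency, `idf = ln((1 + n) / (1 + df)) + 1`, raw term counts and L2
document normalization. The reference classifier is multinomial logistic
regression fit by `nnet::multinom` (zero-initialized, hence
deterministic) with an L2 penalty whose default, 0.5, corresponds to the
conventional unit-strength ridge `0.5 * ||w||^2`: on leave-one-out folds
of small corpora a looser penalty lets the model absorb chance
correlations of filler words and harms held-out behavior. A
`majority_classifier()` provides the practical lower bound, and
`embedding_bag_classifier()` — mean-pooled fixed random embeddings under a
one-hidden-layer tanh network trained by full-batch Adam — supplies a
genuinely nonlinear, differentiable target for gradient-based
attribution. External models (transformers, SVMs, forests) are reachable
through the same adapter contract: anything with
`predict_proba(object, tokens)` over the three classes, e.g. via
`function_classifier()`.

Class imbalance is handled by random oversampling to the majority count.
Oversampling happens *inside* each leave-one-out fold: balancing before
splitting would leak duplicates of the held-out report into its own
training set. One consequence is deliberate: a majority classifier
evaluated through oversampled folds degenerates to a tie-break, so the
pipeline's baseline row is computed directly as the training-corpus
majority class predicted everywhere, which is what a majority baseline
means.

Metrics come from the 3×3 confusion matrix with the zero-division
conventions that make the audit well-defined on degenerate slices: a class
never predicted has precision 0; a class without true members has recall
0 and F1 0. Macro averaging weights the three classes equally (the rare
class matters); the prospective hold-out protocol reports support-weighted
averages instead and excludes classes absent from the test set, as
appropriate when the rare class has no prospective reports.

## The three explainers

All explainers operate on the report's distinct word types (masking a word
removes *all* its occurrences — scores attach to words, not positions),
explain the class the model actually predicted (they never see true
labels), and return the top 5 scores by absolute value with lexicographic
tie-breaks. Ranking by magnitude rather than signed value keeps strong
negative evidence visible; the sign is preserved in the output.

**LIME.** Perturbations are uniformly random word subsets; each perturbed
report is scored on the predicted class and weighted by
`exp(-D²/σ²)` with `D` the cosine distance between presence masks. The
kernel width defaults to `σ = 0.25·√m` for `m` distinct words so that
weights stay non-degenerate as reports grow. A weighted linear surrogate
with greedy forward selection of exactly five words is fit; the selected
coefficients are the scores. `exact = TRUE` enumerates all `2^m` masks,
which is the oracle the sampling regime is tested against.

**Kernel SHAP.** The coalition value `v(S)` is the predicted-class
probability of the report with only the word types in `S` retained. With
`m ≤ 12` Shapley values are computed exactly from the subset-weight
formula; otherwise coalitions are sampled proportionally to the Shapley
kernel `(m-1)/(k(m-k))` and values estimated by least squares with
`v(∅)` fixed and the efficiency constraint
`∑φ = v(full) − v(∅)` eliminated into the design. Efficiency therefore
holds exactly in both regimes.

**Integrated Gradients.** `ig_attribute()` approximates the path integral
of the analytic gradient of the predicted-class probability from an
all-zero baseline. The Riemann sum uses the *midpoint* rule: it estimates
the same integral as the endpoint rule but converges one order faster, so
the completeness identity `∑IG = f(x) − f(baseline)` is met to ~1e-6 at
2000 steps instead of hovering at the 1e-3 scale. For linear models the
attribution is exact at any step count. Per-dimension attributions are
summed to word types (for the TF-IDF model dimensions already are words;
for the embedding bag, token rows are summed over embedding dimensions and
then over occurrences).

Sampling budgets default to 600 masks (LIME) and 1024 coalitions (SHAP)
per report — enough for stable top-5 sets at 20–60-token reports — and are
echoed into the run manifest.

## Verification

The **fidelity** and **deletion** checks re-predict each held-out report
inside the same LOO folds (same derived fold seeds, hence the same
trained models) in three forms: full, only the ≤ 5 important words, and
without them; the two reductions partition the token multiset. Sufficient
explanations keep `acc_only` near `acc_full`; necessary ones collapse
`acc_without`. The package's property tests show the check is
discriminating: a plant-selecting explainer separates the two accuracies
by more than 0.2, while a filler-selecting explainer inverts the pattern —
the failure mode that distinguishes a faithful from an unfaithful
attribution method is detectable at desk scale.

**Alignment scoring** normalizes the five scores by magnitude to shares
summing to one — the source formulation presumes nonnegative scores, but
SHAP/IG emit signed values, and magnitude shares keep category weights
interpretable — then canonicalizes each word through the lexicon's
normalization map (the mechanized form of manually correcting misspellings
and synonyms) and assigns one of five categories by precedence relative to
the predicted class: valid → perhaps valid → wrong list → other-class
lists → unknown. Predicted-class lists dominate the wrong list because a
word the expert endorses for the predicted class is evidence, whatever
else it appears in. Category sums are conserved at 1 per report;
summaries are means ± standard deviations over *all* reports, including
misclassified ones, because the object under audit is the model as it is.

**Cohen's kappa** implements the standard two-rater
`(p_o − p_e)/(1 − p_e)` with the degenerate-marginal convention
`κ = 1` if both raters agree constantly, else 0 when `p_e = 1`.

## Reproducibility

Every stage of `run_pipeline()` draws from `derive_seed(master, stage)`,
a stable string hash, so adding a stage never perturbs earlier streams and
identical configurations reproduce byte-identical JSON artifacts. The
bundled acceptance script runs the audit at a 120-report corpus
(40/77/3 by largest remainder), LOO for both the model and its baseline,
all three explainers, and the full verification layer — sizes chosen so a
complete audit remains a desk-scale computation while leaving every class
with at least two reports per LOO fold.

## Known limitations

- The generator's independence assumptions (words injected independently
  given the label) make the corpus easier than real clinical text; audit
  pass rates here are upper bounds on real-data behavior.
- The embedding-bag network is a stand-in scale of differentiable model;
  auditing a fine-tuned transformer requires wrapping it in the adapter
  and differentiable contracts and is out of scope here.
- Alignment quality is bounded by the lexicon: words the expert never saw
  land in *unknown*, which is a statement about lexicon coverage, not
  model error.
- Kappa here is plain two-rater agreement; multi-round adjudication
  protocols are not modeled.
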