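---
title: "Selective diagnosis by learning to defer with ensemble uncertainty"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selective diagnosis by learning to defer with ensemble uncertainty}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A diagnostic classifier that must label *every* patient will be wrong on
some of them, and in a clinical setting those errors are costly.
Selective prediction offers a third action: for patients where the
automated diagnosis is likely unreliable, *defer* to a human expert.
The goal is the best trade-off between coverage (how many patients are
diagnosed automatically) and accuracy on the automated arm.  `deferral`
implements a two-stage procedure that makes the defer decision from a
deep ensemble's predictive uncertainty, together with the two standard
comparison strategies and the evaluation protocol for all three.

## The model

**Stage one.** K fully connected diagnostic networks with identical
architecture are trained on the same rows, differing only in random
initialisation and minibatch order (`train_ensemble()`).  No
bootstrapping is used; initialisation diversity alone is an effective
estimator of epistemic uncertainty — the component of predictive
uncertainty attributable to the model rather than the data.  For
patient $x_i$ with member positive-class probabilities
$P_k(x_i)$, two summaries are computed (`ensemble_entropy()`,
`diagnostic_entropy()`, both in nats):

$$u_e(x_i) = -\sum_{k=1}^{K} P_k(x_i)\,\log P_k(x_i),$$

a sum of per-member terms that is low exactly when every member is
individually confident, and

$$u_d(x_i) = -\sum_{c \in \{0,1\}} P_c(x_i)\,\log P_c(x_i),$$

the entropy of the class-vote fractions $P_c$ (each member votes its
class by thresholding at 0.5; ties go to the positive class).  $u_d$ is
zero precisely when the members vote unanimously and $\log 2$ when they
split evenly.  Note that $u_e$ is deliberately *not* normalised — the
$P_k$ do not form a distribution over $k$ — and the package implements
it in exactly this form; a proper per-member average,
`mean_binary_entropy()`, is exposed under its own name for users who
want it.  Since every threshold in the package is swept rather than
fixed, the base of the logarithm is immaterial; natural log is used
throughout.

**Stage two.** A defer network — fully connected, two hidden layers of
100 nodes by default — receives the $K + 2$ inputs
$(P_1, \dots, P_K, u_e, u_d)$ and has $C + 1 = 3$ outputs: class 0,
class 1, defer (`train_defer_network()`).  It is trained with the
weighted defer loss (`defer_loss()`)

$$\mathrm{loss}(x, t) \;=\; \alpha\,\mathrm{CE}(t) + \mathrm{CE}(\mathrm{defer}),$$

where $\mathrm{CE}(j)$ is the cross-entropy of softmax output $j$.  No
defer labels exist; the constant defer term prices the expert's
involvement, and $\alpha$ sets the exchange rate: **small $\alpha$
defers more patients, large $\alpha$ fewer**, with the transition near
$\alpha = 1$.  At triage time the decision is the argmax of the three
softmax outputs, with ties broken toward defer — the conservative
action for a diagnostic aid (`triage()`).

### Why alpha weights the target term

The literature writes this loss with the weight on the defer term.  We
place it on the target term by default (`alpha_on = "target"`) for a
behavioural reason: every reported use of the loss — decreasing the
weight to encourage deferral, defer rates that fall as the weight rises
through values above 1 — requires the target-term placement.  Under the
defer-term placement, the per-sample optimum puts
$p_\mathrm{defer}/p_\mathrm{target} = \alpha$, so any $\alpha > 1$
would defer essentially everything, which is not how the procedure is
described to behave.  The transposed, literal form remains available
via `alpha_on = "defer"`; the two coincide exactly at $\alpha = 1$, and
both are unit-tested against an independent cross-entropy oracle.

Inside the optimiser the loss is divided by $1 + \alpha$.  A positive
scaling does not change the minimiser; it keeps gradient magnitudes
comparable across an $\alpha$ grid so that one learning rate serves the
whole sweep.  The exported `defer_loss()` returns the unnormalised
value.

## Comparison algorithms

* **LD** (learning to defer *without* uncertainty): the diagnostic
  network itself, its output widened from 2 to 3, trained end-to-end on
  raw features with the same defer loss and the same hyperparameters as
  the unmodified diagnostic network (`train_ld()`).  LDU and LD share
  one loss implementation.
* **DT** (direct triage by uncertainty): defer every patient whose
  diagnostic entropy strictly exceeds a threshold; diagnose the rest by
  majority vote (`triage_dt()`).  The strict inequality gives DT its
  structural ceiling: at threshold 0 the deferred set is exactly the
  patients with nonzero entropy, so patients on whom the members vote
  unanimously — however wrongly — can never be deferred.  An
  ensemble-entropy variant is provided (`entropy = "ensemble"`).

## Evaluation protocol

`compute_metrics()` reports the defer rate; positive-class F1,
accuracy, sensitivity and specificity over the non-deferred patients;
and an *overall* F1 over all patients computed under the assumption
that every deferred patient receives the correct diagnosis from the
expert.  Degenerate denominators yield `NA` plus an entry in `flags`,
never a silent 0.  `sweep_defer()` traces the coverage–accuracy curve —
one freshly trained model per control value, no warm starts — and
`operating_point()` selects the cheapest record reaching a target F1.
All rates are fractions internally; percent formatting belongs to the
reporting layer.

## The synthetic cohort generator

Real credentialed clinical datasets cannot ship with a package, so
`simulate_cohort()` generates class-balanced cohorts that reproduce the
three regimes that matter for deferral, with a `subgroup` tag carried
for evaluation only (models never see it):

* **easy** — class-specific Gaussian centroids separated by
  `class_separation` (default 10 feature units at `noise_sd = 1`, i.e.
  a 5-sigma margin): the learnable majority.
* **ambiguous** — both classes drawn from one shared centroid; the
  Bayes error inside the region is 0.5.  Deferring these patients is
  the only way to raise accuracy on them.
* **overconfident_wrong** — labelled $y$ but placed at `ocw_shift`
  (default 0.75) times the centroid of class $1 - y$: feature-wise they
  belong to the other class, so every well-trained classifier is
  confidently wrong and member votes are unanimous ($u_d = 0$).  The
  0.75 placement keeps them roughly 2.5 noise standard deviations on
  the wrong side of the boundary — unambiguously "in" the opposite
  class yet at measurably less extreme member probabilities than
  genuine easy patients, which is precisely the signature stage two can
  exploit and an entropy threshold cannot.

Class balance is built into generation (real cohorts are typically
balanced by down-sampling the majority class; balanced generation is
the synthetic equivalent).  An optional `n_modes > 1` scatters each
class over several orthogonal centroids to emulate heterogeneous
presentation.  Splitting is stratified 70/30 by default
(`split_cohort()`).

What the generator does **not** emulate: raw clinical modalities (text,
images), label noise beyond the overconfident-wrong construction,
covariate shift between splits, and within-class correlation structure.
Passing tests on these cohorts therefore demonstrates the *mechanisms*
— monotone coverage control, the entropy-threshold ceiling, selective
deferral of hard subgroups — not performance on any real clinical task.

## Study conditions used by the tests and the acceptance script

Two standard conditions, both with 16 features and the defaults above:

* **Mixed difficulty** (fractions 0.6 / 0.3 / 0.1, n = 1,000 per
  class): used for the monotonicity and enrichment checks.  Members:
  two hidden layers of 32, 10 epochs of Adam at learning rate $10^{-3}$
  with weight decay $2 \times 10^{-3}$; K = 10.  Defer network: 100+100,
  60 epochs of Adam at $10^{-3}$.
* **Zero-diagnostic-entropy** (0.9 / 0 / 0.1, n = 3,000 per class):
  the regime where every vote is (near-)unanimous and DT is
  structurally blind.  Members: two hidden layers of 64, **4 epochs**,
  Adam at $9 \times 10^{-4}$, **no weight decay**; K = 25.  Defer
  network: 100+100, 20 epochs at the same rate.  The brief,
  unregularised member training mirrors the reference configuration for
  structured-data diagnosis (a few epochs, zero weight decay) and is
  what makes the condition informative: members saturate on genuinely
  easy patients while remaining measurably less extreme on the
  confidently-wrong subgroup, so the probability vector carries a
  signal that the raw features give the end-to-end LD defer head no
  easy access to in so few epochs.

These sizes keep the full test suite within minutes on one CPU while
leaving every comparison statistically meaningful (the test split holds
600 and 1,800 patients respectively).  Where two algorithms are
compared at a matched F1, the target is the best value both attain at
moderate deferral, matched at the two decimal places such selected-F1
comparisons are conventionally reported at.  K defaults to 50 in
`train_ensemble()` — the reference ensemble size — but the checks use
K = 10 and K = 25; all operations are written for arbitrary K of at
least 2.

## Numerical and design choices

* **Engine.** All learners are small multilayer perceptrons (ReLU
  hidden units, softmax head) trained by minibatch SGD with momentum or
  Adam, implemented in vectorised base R inside the package.  The defer
  loss needs custom gradients, and at these problem sizes (thousands of
  rows, tens of columns) matrix-level R is fast and keeps the gradient
  code auditable; the backpropagation is unit-tested against finite
  differences.  Inputs are standardised to training mean and standard
  deviation inside every learner (constant columns guarded), including
  the stage-two network — whether stage two standardises its inputs is
  unstated in the source procedure, and standardisation is the
  convention that makes one learning rate portable across fixtures.
* **Conventions.** `0 log 0 = 0` in every entropy; member votes
  threshold at $p \ge 0.5$ with ties to the positive class; triage ties
  break toward defer; the DT comparison is strict (`>`), so threshold 0
  realises the ceiling semantics exactly.
* **Seeds.** One integer seeds everything: member $i$ of an ensemble
  uses `master_seed + i - 1`; a sweep's stage-two seed equals its
  pipeline seed (shared across the grid so the sweep isolates the
  effect of $\alpha$); generation and splitting restore the caller's
  RNG state afterwards.
* **In-sample versus cross-fitted stage two.** The single-split
  procedure — stage two trained on the same rows the ensemble saw — is
  the default, matching the described two-stage design.  At small
  sample sizes in-sample member probabilities are optimistically
  sharp, which shifts the defer network's training inputs relative to
  what it meets at prediction time; `stage2_features_crossfit()` (and
  `sweep_defer(cross_fit = TRUE)`) removes the shift by scoring each
  training fold with an ensemble fitted on the remaining folds.  It
  costs `folds` extra ensemble fits and is worth it when the training
  split is small.
* **Degenerate sweeps.** Records with defer rate 0 or 1 are kept and
  flagged (`all_deferred`, `f1_undefined`), so sweep tables stay
  rectangular; at full deferral the overall F1 is 1 by definition of
  the deferred-assumed-correct convention, and the non-deferred F1 is
  undefined rather than 0.
* **One model per grid point.** Sweeps never warm-start across
  $\alpha$; each grid point is an independently trained model, which is
  what makes the defer-rate-versus-$\alpha$ monotonicity a property of
  the loss rather than of an optimisation path.

## Known limitations

* Binary tasks only ($C = 2$); the multiclass extension is mechanical
  (the loss and triage rule already generalise) but untested here.
* The expert is modelled as always correct and of constant cost — the
  overall-F1 convention and the constant defer term encode exactly
  that.  Modelling expert uncertainty would require per-patient expert
  labels.
* Aleatoric uncertainty is not estimated separately; the two entropies
  conflate it with epistemic uncertainty in the ambiguous regime
  (which is why the ambiguous subgroup is deferred first — the desired
  behaviour here, but not a decomposition).
* At desk scale the LD baseline is a strong competitor: with a simple
  tabular geometry, generous member training and weight decay, an
  end-to-end defer head can equal or beat the two-stage procedure.
  The comparative advantage of uncertainty-aware deferral appears in
  the brief-training, unregularised regime described above — consistent
  with reports that the advantage is largest for complex backbones
  whose end-to-end defer heads are hardest to train.

## A worked example

```{r, eval = FALSE}
library(deferral)

parts <- simulate_cohort(n_per_class = 1000, seed = 1) |>
  split_cohort(train_fraction = 0.7, seed = 1)

base_spec <- base_classifier_spec(hidden = c(32, 32), epochs = 10,
                                  learning_rate = 1e-3,
                                  weight_decay = 2e-3, optimizer = "adam")
defer_spec <- defer_model_spec(epochs = 60, learning_rate = 1e-3,
                               optimizer = "adam")

sw <- sweep_defer(parts$train, parts$test, "ldu",
                  grid = c(0.6, 1, 1.3, 1.7, 2.5), seeds = 1:3, k = 10,
                  base_spec = base_spec, defer_spec = defer_spec)
autoplot(sw)
operating_point(sw, target_f1 = 0.85)
```
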