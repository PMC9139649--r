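---
title: "Fuzzy rank level fusion: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fuzzy rank level fusion: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frlf)
```

## The problem

An ensemble of $N$ classifiers evaluates one input and each model $M_i$
emits a row of confidence scores $CS^{M_i}_c$ over $C$ classes (softmax-style:
nonnegative, summing to one). Decision-level fusion must turn these $N \times C$
scores into a single predicted class. Plain averaging (sum rule) treats a
model that says 0.51 the same way as one that says 0.99 up to a linear
weight; voting throws the confidence away entirely. Fuzzy rank level fusion
(FRLF) sits between the two: it converts each confidence into a *fuzzy rank*
that measures proximity to the ideal confidence 1, keeps the actual scores
for the classes each model genuinely supports, and penalises every class a
model leaves out of its top-K set.

The motivating application is binary screening of dopamine-transporter SPECT
(DaTscan) images for Parkinson's disease, where the base learners are
CNNs and the cost of a misclassification is clinical; but nothing in the
machinery is specific to that domain beyond the defaults.

## The model

With normalized scores ($\sum_c CS^{M_i}_c = 1$ for every model $i$), the
fuzzy rank of class $c$ under model $M_i$ is the complement of a Gaussian
density centred at the ideal confidence:

$$R^{M_i}_c = 1 - \exp\!\left(-\frac{(CS^{M_i}_c - 1)^2}{2\sigma^2}\right),
\qquad \sigma^2 = 1 \text{ by default.}$$

$R = 0$ at full confidence (the analogue of conventional rank 1) and rises
monotonically to $1 - e^{-1/2\sigma^2} \approx 0.393$ as the confidence falls
to zero. Each model contributes its top-K set $K^{M_i}$ — the $k$ classes
with smallest fuzzy rank. Aggregation over models substitutes fixed
penalties for classes outside a model's top-K set:

$$RS_c = \sum_{i=1}^N \begin{cases} R^{M_i}_c & c \in K^{M_i} \\
P^R & \text{otherwise} \end{cases}
\qquad
CSS_c = 1 - \frac{1}{N}\sum_{i=1}^N \begin{cases} CS^{M_i}_c & c \in K^{M_i} \\
P^{CS} & \text{otherwise,} \end{cases}$$

and the final score $FS_c = RS_c \times CSS_c$ is minimised:
$\hat{c} = \arg\min_c FS_c$. Both factors are small exactly when the models
rank the class highly *and* give it real confidence mass, so the product
rewards agreement in both senses; the penalties keep a class that most
models exclude from winning on one model's enthusiasm.

The aggregation formula is worth a note: the confidence penalty is read as
replacing the confidence term *inside* the mean before complementing
($CSS_c$ as written above). The alternative reading — penalising after the
complement — fails to reproduce the worked example below, while this one
matches it exactly, and it is the reading under which the penalties "push a
class towards losing": substituting a small $P^{CS}$ for a large confidence
raises $CSS_c$.

### Worked example

Two models, two classes, $k = 1$, default penalties:

```{r}
s <- score_matrix(rbind(c(0.9, 0.1), c(0.6, 0.4)))
frlf_fuse(s)
```

Both models put class 1 in their top-1 set, so class 1 collects its true
ranks ($0.00499 + 0.0769 = 0.0819$) and its true mean confidence
($CSS = 1 - 0.75 = 0.25$); class 2 collects only penalties
($RS = 2 \times 0.33 = 0.66$, $CSS = 1 - 0.05 = 0.95$). The final scores
$0.0205$ vs $0.627$ select class 1.

## Parameters and defaults

| parameter | default | meaning |
|---|---|---|
| `k` | 1 | size of each model's top-K set. With binary classes and `k = 1` each model backs exactly its argmax. `k = C` disables the penalties entirely, and with one model the rule then reduces to plain argmax. |
| `rank_penalty` ($P^R$) | 0.33 | rank substituted outside the top-K set; dimensionless, on the fuzzy-rank scale $[0, 0.393]$ — i.e. close to the worst attainable rank at unit variance, but not beyond it. |
| `conf_penalty` ($P^{CS}$) | 0.05 | confidence substituted outside the top-K set, on the probability scale. Small, so excluded classes keep a near-maximal complement. |
| `variance` ($\sigma^2$) | 1 | width of the Gaussian; larger values flatten the rank curve and compress differences between confident and unconfident scores. |

The default penalties are the pair tuned for the binary DaTscan task; they
are exposed (API, config file and CLI flags) rather than hard-coded because
they are dataset-tuned hyperparameters, not constants of the method.

For the binary case with `k = 1` and defaults, unanimity is provable: if all
$N$ models put their larger confidence $p > 0.5$ on the same class, the
losing class scores $FS = 0.33N \times 0.95$, which exceeds the winner's
$FS \le N \cdot R(p) \cdot (1 - p)$ for every $p \in (0.5, 1]$; the test
suite asserts this over a dense grid of $p$.

## Baseline combiners

The sum rule ($\arg\max_c \sum_i CS^{M_i}_c$), product rule
($\arg\max_c \prod_i CS^{M_i}_c$) and majority voting (each model votes for
its argmax) are implemented over the same input type for comparison. Two
under-specified corners were fixed deterministically:

* **all argmax/argmin ties** break towards the lowest class index;
* **vote ties** in majority voting cascade to the sum rule restricted to the
  tied classes, then to the lowest index;
* **zeros in the product rule** annihilate a class by default — no epsilon
  flooring is applied unless the user passes `floor`, since silent flooring
  changes the rule being reported.

## Metrics

Binary diagnostics follow the usual confusion-count definitions
(accuracy, precision, sensitivity, specificity, F1). Two choices matter for
reproducing published tables:

* a metric with a zero denominator (e.g. precision with no positive
  predictions) is **undefined (`NA`)**, never 0 — silent zeros corrupt
  summary tables;
* percentages are rendered by **rounding half-up to two decimals**
  (`percent` field), since printed tables mix rounded and truncated values;
  comparisons against printed values should use a ±0.01 percentage-point
  tolerance. An epsilon of $10^{-9}$ guards the half-up rule against binary
  representation artefacts (e.g. $127/129 \cdot 100 = 98.4496\ldots$ stored
  as $98.4499\ldots$).

`counts_from_rates()` inverts printed sensitivity/specificity back to
integer confusion counts given the class sizes — printed rates at two
decimals identify the counts uniquely for test sets of this size, which
makes published tables internally checkable.

## Preprocessing pipeline

The imaging front-end mirrors the standard DaTscan preparation: volumes of
91 slices × 109 × 91 voxels, from which one mid-striatal axial slice is
taken (default index 41, treated as **1-based** — the indexing convention is
exposed as a parameter since prose descriptions rarely state it), the black
background is cropped to the tight bounding box of pixels above a threshold
(default 0, strict black; the crop rule itself is an interpretation — brain
size varies between subjects and no published crop box exists), then a
**bilinear** resize to 224 × 224 (the interpolation kernel is a choice; no
source names one) and a min–max rescale to $[0, 1]$. Degenerate inputs are
handled by convention rather than error: an all-black slice crops to its
1 × 1 centre pixel, and a constant slice rescales to all zeros.

Brightness adjustment over $[0.1, 1.5]$ is treated as a *training-time
augmentation* (the range matches common augmentation configs) and is never
applied by the evaluation path. The 80:20 `split_dataset()` is
non-stratified by default — a plain seeded shuffle with
`round(test_fraction * n)` held out, which reproduces the 86/43 composition
of a 645-image dataset only up to sampling fluctuation, exactly as a plain
random split would — with an optional stratified mode.

Volumes are read from NIfTI (via RNifti) or built in memory; slice export is
8-bit PNG, or 16-bit TIFF where quantization loss matters.

## The synthetic-score generator

No public simulation accompanies the method, so the generator's
distributional choices are this package's own. Each sample draws a true
label at prevalence 86/129 ≈ 0.667 (the composition of the motivating test
set, so simulated confusion tables resemble that scale). Each model
independently favours the true class with its configured accuracy, otherwise
a uniformly chosen wrong class. The favoured class receives confidence

$$p = 0.5 + 0.5\,B,\qquad B \sim \mathrm{Beta}(\text{concentration},\, 1),$$

and the remaining $1 - p$ is split over the other classes by a symmetric
Dirichlet draw. Keeping $p > 0.5$ guarantees the favoured class is the
argmax, so the realised per-model accuracy equals the configured one in
expectation — accuracy and calibration sharpness are independently tunable.
The default concentration of 10 puts typical top confidences near 0.95,
a realistic sharpness for a well-trained softmax classifier. Everything is a
deterministic function of the config seed, and the generator restores the
session RNG state.

What the simulation does *not* emulate: correlated errors between models
(real CNNs trained on the same images err on the same hard cases, which
shrinks ensemble gains), miscalibration drift, and any image content. Tests
that pass on simulated scores therefore demonstrate the correctness and the
qualitative ensemble-gain behaviour of the fusion rules, not the accuracy
achievable on real DaTscan volumes.

```{r}
cfg <- simulation_config(2000, n_models = 4,
                         model_accuracies = rep(0.93, 4), seed = 1)
simulate_confusion_profile(cfg, "frlf")
```

With four independent models at accuracy 0.93, fused accuracy lands near
0.985–0.99 — the majority-of-independent-voters bound
($\sum_{j\ge 3}\binom{4}{j}0.93^j 0.07^{4-j}$ plus the split 2–2 cases)
predicts the gain; the property suite confirms it across ten seeds at
$n = 5000$.

## Numerical contract

Aggregation is in double precision; the argmin/argmax comparisons are exact
on the computed values (no tolerance), which together with the lowest-index
tie-break makes every decision deterministic. The vectorized implementation
is required by the test suite to agree with a scalar, loop-by-loop reference
implementation to $10^{-12}$ on a thousand random seeded score matrices
($N \in 1..5$, $C \in 2..6$) — sizes chosen to cover the degenerate
single-model and binary cases while keeping the default test run under a
minute for this suite. Score files round-trip losslessly: numbers are
written with 17 significant digits in both CSV and JSON.

## Known limitations

* Binary metrics only; multiclass fusion works, but evaluation of more than
  two classes is out of scope.
* The penalties are global scalars. Per-class penalties would be a
  straightforward extension but there is no published per-class tuning to
  reproduce.
* `counts_from_rates()` assumes the printed rates round to a unique integer
  count — true for two-decimal rates on class sizes up to a few thousand.
* The simulator's independence assumption is optimistic; treat its ensemble
  gains as upper bounds on what correlated real models would give.
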