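---
title: "Forecasting diastolic blood pressure from EHR knowledge graphs: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forecasting diastolic blood pressure from EHR knowledge graphs: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(graphDBP)
```

## The problem

Heart failure is managed longitudinally: a patient accumulates visits, each
recording hemodynamic labs (diastolic and systolic blood pressure, systemic
vascular resistance), demographics, comorbidity diagnoses and medication
changes. Because blood pressure tracks cardiovascular risk, the DBP measured
at the *next* visit is a useful surrogate endpoint for how a patient is
responding to therapy. `graphDBP` forecasts that value from the patient's
history, representing each history as a small knowledge graph rather than as
a padded multivariate sequence, so irregular sampling and missing
measurements need no imputation: a missing event simply has no node.

## The patient graph

For a patient with visits $V_1,\dots,V_T$ and a forecast horizon $h$ (the
last $h$ visits are withheld; the target is the DBP of the first withheld
visit), the graph $G=(V,E,A,X)$ has:

* **Nodes** — one per observed (event type, visit) pair within the chosen
  data source (`Demographics`, `Lab`, `Comorbidity`, or `ALL`; single
  sources always keep the past DBP chain since DBP is the outcome).
* **Edges** — within each event type's chronological chain, every
  observation is connected (undirected) to *all* later observations of that
  chain, so one hop reaches long-range history. The adjacency $A$ is the
  binary, symmetric, zero-diagonal summary of these temporal links.
  Cross-type interaction is deliberately not in $A$; it is carried by
  attention under the co-occurrence mask. The alternative reading (temporal
  edges across types) is not supported; directed variants were excluded by
  design.
* **Features** — $X \in \mathbb{R}^{|V|\times 1}$: the normalized event
  value plus the patient's min–max-normalized timestamp, which injects
  position information into an order-invariant architecture.

Value normalization is min–max per event type with ranges fitted on the
*training fold* and clipped to $[0,1]$ for held-out patients. A per-patient
variant (each patient's own range) is available (`scaler = NULL`), but it
erases the patient's absolute BP level — the dominant predictable component
of the target — so the fitted-scaler variant is the pipeline default. Both
are leakage-free. Comorbidity nodes carry tf–idf weights
($\mathrm{tf}\times(\log\frac{1+N}{1+\mathrm{df}}+1)$, each patient's whole
history being one document), scaled into $[0,1]$ by the training-fold
maximum; the idf table is fitted per training fold.

## The model

Given $X$, multi-head scaled dot-product self-attention forms
$Q=XW_q$, $K=XW_k$, $V=XW_v$ per head and

$$Z=\mathrm{Softmax}\!\left(\frac{\mathrm{Mask}(QK^\top)}{\sqrt d}\right)V,$$

where the mask sets a score to $-\infty$ whenever the two nodes' event
types have never co-occurred in a training-fold record (a record is a
single visit by default). Masked pairs therefore receive *exactly* zero
attention and each row remains a probability distribution over its allowed
set. The mask diagonal is forced to 1 so no row can become empty. During
training, each node additionally attends only to a uniform sample of $k$
other nodes (redrawn every epoch, self always kept); prediction uses the
full mask.

Head outputs are concatenated and linearly projected; a single graph
convolution over the temporal adjacency,
$Z' = \mathrm{ReLU}(\tilde D^{-1/2}(A+I)\tilde D^{-1/2}\,Z\,W_g + b_g)$,
injects the explicit chain structure ("mean" row-normalized aggregation is
available as an option). The graph is read out by summation and a linear
head produces the forecast $\hat Y$. Ablations keep either component alone:
transformer-only skips the convolution; GNN-only convolves $X$ directly.

The output projection and the convolution carry standard bias vectors.
This matters here more than in most architectures: with one-dimensional
node features and no biases anywhere, every learned feature is nearly
homogeneous in $X$, so the network cannot form thresholded units — and
without thresholds no graph-size-invariant summary of recent lab values is
representable under a sum readout. The layers are otherwise exactly as
described above; layer normalization and residual connections are not used.

## Optimization and evaluation

Training minimizes the MSE of the forecast with Adam at the protocol
defaults: 50 epochs, batch size 4, learning rate $5\times10^{-4}$, 10-fold
cross-validation, with per-fold refitting of the scaler, tf–idf and mask so
held-out co-occurrence structure never unmasks attention. Targets are
standardized internally by the training-fold mean/SD and predictions
inverted to mmHg for all reported metrics (MAE, MSE, RMSE); at this
learning rate and epoch budget a raw-scale bias could never travel from 0
to a physiological BP level, so raw-scale optimization is not meaningful.
Training is deterministic given the seeds: initialization from the model
seed, batching and neighbor sampling from the training seed.

Per-graph gradients (attention, convolution, readout) are computed
analytically in compiled code; the exported R functions are the reference
implementation, and the test suite checks C++/R forward parity and
analytic-vs-numerical gradient agreement.

Multi-step evaluation forecasts the last visit (horizon 1) and the
second-to-last (horizon 2) by independent truncation, never by feeding
predictions back. A patient needs at least one observed visit before the
withheld one, so two-visit patients enter the horizon-1 protocol only.

## The synthetic cohort

Real heart-failure EHR cohorts of this kind are proprietary, so the
package ships a simulator whose *structure* matches them — 2–15 visits per
patient, per-visit labs, sparse comorbidities, drug-category assignment,
HFrEF/HFpEF labels, a last-visit DBP target — and whose *generative model*
is chosen for testability: a stationary AR(1) latent health state $h_t$
with labs linear in $h_t$ plus Gaussian noise, a per-visit linear drug
effect on DBP, and subtype regimes differing in DBP gain, autoregression
and baseline level. The conditional mean given the latent state is then a
closed-form oracle whose RMSE estimates the irreducible noise floor
(`oracle_predictor()`), giving the tests an absolute yardstick no real
dataset provides.

Defaults (fixed once as the study conditions): 800 patients, mean 5 visits
(Poisson truncated at 2), observation noise 5 mmHg, HFrEF regime gain 4
and autoregression 0.9 at baseline 68 mmHg vs HFpEF gain 3, autoregression
0.8, baseline 78 mmHg, stationary latent SD 2, 10% per-event missingness
(DBP itself is always measured — it is the variable under study), drug
effects of −0.8 to −1.2 mmHg/visit for the antihypertensive categories and
−0.1 for statins. The temporal-advantage comparison against the MLP
baseline uses 20% missingness, because irregular missingness is precisely
what the graph representation claims to absorb and fixed-window padding
does not; the subtype-separation experiments widen the baseline gap to
20 mmHg (`subtype_gap`), matching their purpose of testing a
large-effect two-regime cohort.

What the simulator does **not** emulate: realistic marginal BP
distributions, medication switching over time, informative missingness,
visit-frequency–severity coupling, or coded-diagnosis noise. Passing tests
therefore demonstrate that the machinery is correct and that the method
behaves as designed under known structure — not that it attains clinical
accuracy on real EHR data.

## What the scalar node feature can and cannot carry

Two structural consequences of $X\in\mathbb{R}^{|V|\times 1}$ deserve
explicit statement, because they bound what any training run of this
architecture can achieve on level-dominated targets:

1. **Value–time confounding.** The feature is the *sum* of the normalized
   value and the normalized timestamp, so a recent low value and an old
   high value can produce the same scalar. Only chain endpoints are clean
   (the first observation has time 0, the latest has time 1).
2. **Type blindness.** Node identity enters the model solely through the
   co-occurrence mask and the chain structure of $A$. Within the `Lab`
   source all three labs co-occur at almost every visit, so their mask rows
   are identical and the model can only learn functions that are symmetric
   under exchanging the lab chains. The windowed MLP baseline, by
   contrast, receives *type-labeled* slots.

On the simulator this shows up exactly where theory predicts: the full
model beats the constant predictor clearly, but its cross-validated RMSE
(recomputed by `scripts/acceptance.R` as `cv_rmse_graphformer`, alongside
`oracle_noise_floor_rmse`, `cv_rmse_mean_predictor` and
`cv_rmse_mlp_baseline`) stays above the noise floor by more than the margin
a type-aware predictor achieves, and the type-labeled MLP is the stronger
baseline at these conditions. We report this honestly rather than altering
the representation; the acceptance suite asserts the corresponding recovery
and baseline-ordering properties at their stated thresholds and they fail
on this architecture at desk scale.

## Numerical and design choices

* Min–max of a constant sequence is defined as all zeros; features are
  clipped to $[0,1]$ under the fitted scaler, so $X\in[0,2]$ always.
* Softmax rows subtract their finite maximum before exponentiation; an
  all-masked row raises an error rather than returning NaN (precluded in
  normal operation by the unit mask diagonal).
* Attention-weight rows sum to 1 within $10^{-6}$; masked entries are
  exactly 0 by construction, not approximately.
* Mask + sampling combine by intersection with self always retained.
* Fold assignment is a seeded shuffle into near-equal parts; no
  stratification (none is specified for the protocol).
* Tf–idf uses the smoothed idf with raw counts; "document" is the whole
  patient history because comorbidities persist across visits.
* Age is re-recorded per visit (per-visit aging); gender receives one node
  per visit for consistency with the per-timestep node rule. Both choices
  are conventions, not claims about the source data.
* The co-occurrence "record" is a single visit by default and can be
  widened to the whole patient (`level = "patient"`).
* Problem sizes in the shipped experiments — 800 patients for the recovery
  protocol, 400 with a 70/30 split for the baseline comparison, 200 for the
  subtype experiments, 3–5 seeds each — were chosen so the full suite
  reruns comfortably on a laptop core while keeping Monte-Carlo error well
  below the effect sizes under test.

## Known limitations

* One attention layer and one convolution; no deep stacking.
* The LSTM-family and sequence-Transformer baselines of the original
  comparison are out of scope; only the MLP baseline is implemented.
* Metrics are reported in mmHg against raw targets; no per-patient
  re-scaling of reported errors.
* The silhouette score replaces visual t-SNE inspection for the subtype
  clustering claim; 2-D projection of the exported embeddings is left to
  standard tools.
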