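---
title: "Bayesian logic-operator networks: models, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian logic-operator networks: models, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(balonn)
```

This vignette is the package's own account of its science: the model
family, the statistical machinery, every tunable that matters, and what the
synthetic experiments do and do not show.

## 1. The model family

All three variants share one feed-forward topology for the two-task
heart-failure problem: 10 input features, hidden widths 10–4–3, and a
2-unit sigmoid head whose columns are the binary heart-failure class
(`hf`, on (0, 1)) and the ordinal therapy length (`tl`, sigmoid rescaled
×3 to span the 0–3 class grid — the ordinal task is handled as a
regression with a rounding post-processing step, which preserves the
notion of distance between classes).

* `dnn` — deterministic dense layers, ReLU hidden activations; trained
  with Adam (learning rate 0.08, 400 epochs) on mean squared error.
* `bnn` — the same stack with every layer variational; Adam (0.008,
  300 epochs) on the negative log-likelihood plus KL.
* `balonn` — a variational 10→10 input layer with squashing activation,
  a *frozen* logic block (widths 10→4→3), and a variational 3→2 head.
  Only the first and last layers train; the logic block is immutable data.

### Squashing activations and Łukasiewicz gates

The squashing function
$S_\beta(x) = \frac{1}{\beta}\ln\frac{1+e^{\beta x}}{1+e^{\beta(x-1)}}$
is evaluated as `(softplus(βx) − softplus(β(x−1)))/β` with the stabilized
softplus `max(z,0) + log1p(e^{−|z|})`, which is exact for arguments far
beyond ±700. Three provable properties anchor the test suite:
the complement identity $S(x)+S(1-x)=1$ (hence $S(\tfrac12)=\tfrac12$),
monotonicity for $\beta>0$, and the uniform bound
$\sup_x |S_\beta(x)-\mathrm{clip}(x,0,1)| = \ln 2/\beta$, attained at the
kinks $x\in\{0,1\}$. Because the deviation bound composes additively, a
two-layer gate circuit at $\beta=100$ is crisp to about $2\ln2/100$.

Gates are perceptrons with frozen Łukasiewicz parameters: k-ary AND has
weights 1 and bias $-(k-1)$, OR weights 1 and bias 0, NOT weight −1 and
bias +1, and joint negation (NOR) weights −1 and bias +1. The k-ary
generalizations are the standard t-norm/t-conorm extensions of the binary
table. At $\beta = 1000$ every gate reproduces its classical truth table
after rounding. One typographic point: the printed form of the squashing
denominator is ambiguous between $e^{\beta x - 1}$ and $e^{\beta(x-1)}$;
only the latter satisfies the complement identity and the cutting-function
limit, so that reading is adopted. Likewise the gate table's last row
("not x and not x") is read as the joint negation NOR, the only operator
consistent with its printed weight/bias pair.

$\beta$ defaults to 10 in training (gradients survive: the derivative
$S'_\beta(x)=\sigma(\beta x)-\sigma(\beta(x-1))$ vanishes exponentially
outside $[0,1]$ for large $\beta$) and 100 for crisp evaluation. The block
topology is explicit configuration — the default mirrors the exemplary
clinical gate formulas with conjunctions/disjunctions of small input
groups — because no canonical gate count exists for this problem.

### Variational layers

Each trainable weight carries an independent Gaussian posterior
$N(\mu, \mathrm{softplus}(\rho))$ and a Gaussian prior with fixed scale
$\sigma_{pr}$ (default 1.5). The objective per gradient step is the
standard two-term variational bound: data negative log-likelihood (output
scale fixed at 1.0) plus `kl_weight` × closed-form KL, with
`kl_weight = 1/n_train` (per-observation ELBO scaling). One weight sample
per training step (plain reparameterization, not local reparameterization);
N-sample averaging is reserved for prediction, mirroring the idea that the
sampled models *are* the prediction.

Choices the problem statement left open, decided once:

* **Mean-field factorization** — keeps the KL closed-form and matches the
  dense-variational-layer convention of the deep-learning libraries this
  design imitates.
* **Posterior init**: means $\sim N(0, 0.1)$, scales set to
  $\sigma_{po}$ (default 1.0) through the softplus offset.
* **Trainable prior**: the published parameter table lists it as true while
  the accompanying sensitivity discussion says the logic variant does not
  accept trainable priors — a genuine contradiction in the source material.
  The default follows the parameter table (prior *means* trainable, prior
  scale fixed at $\sigma_{pr}$); `trainable_prior = FALSE` freezes the
  prior bit-exactly.
* **Output scale 1.0 for both heads** on their own class scales. A side
  effect is that the TL head's squared residuals (range 0–3) would dominate
  an MSE objective 9:1; the `dnn`'s MSE is therefore computed on the unit
  (pre-scaling) output range of each head, implementing equal task
  weighting. The negative log-likelihood keeps the fixed unit scale on the
  class grid itself, as stated.

### Optimization

Adam with the standard moment constants. The default batch size is 32 —
the usual stochastic regime for these optimizers; full-batch training
caps the total movement of any parameter at roughly
`learning_rate × epochs`, which at 0.008 × 300 cannot even move a weight
mean from 0 to 2, and is available as `batch_size = "full"` where that
persistence is wanted (see the sweep below). Dense layers use He-normal
initialization with small positive biases; the narrow 10–4–3 ReLU trunk
can still die for an unlucky initialization seed at learning rate 0.08 —
an honest property of the baseline architecture that the seeded runs make
reproducible rather than hide. Training aborts with the epoch and term
named if the loss leaves the finite range.

## 2. Uncertainty-aware validation

For each patient and task the model is run $N = 1000$ times with fresh
posterior draws, giving the sample matrix $f_{ij}$. The statistics:

* $\phi_i = |\frac{1}{N}\sum_j f_{ij} - O_i|$ — the printed definition of
  this distance carries a garbled radical, but the accompanying text defines
  it as the distance between the average and the target, which is what is
  implemented (for scalars the squared-then-rooted reading is identical).
* $Pr_i = \mathbf{1}[\phi_i < Tr]$, strict inequality. Tolerances:
  $Tr_{HF} = 0.7$ (a majority of one binary value) and $Tr_{TL} = 1.2$
  (accepts roughly two adjacent classes on the 0–3 grid). Sensitivity
  sweeps conventionally tighten the binary tolerance to 0.6; both are
  arguments.
* Micro-averaged precision $P = \sum_i Pr_i / M$ and the error. The error
  formula as printed is $1 - \sum\phi_i/M$, which *rewards* large
  distances; the package's default is the mean distance $\sum\phi_i/M$
  (0 for perfect prediction) with the printed complement form available as
  `mode = "printed"` — both are reported side by side rather than silently
  choosing.
* Traffic lights: green if the sample median, rounded to the task's class
  grid, equals the target; blue if not green but the target lies inside the
  central 95% interval of the draws; red otherwise. The 95% level is an
  operationalization of "target inside the predicted distribution" and is
  configurable.

Two structural facts the tests exploit: precision is non-decreasing in the
tolerance (immediate from the indicator), and tolerance-precision always
dominates exact rounded-match accuracy, because a rounded match forces
$\phi \le 0.5 < Tr$ at the default tolerances — this inequality is the
formal content of the claim that modeling epistemic uncertainty raises
precision by accepting ambiguous predictions as true. For a deterministic
model the machinery degenerates cleanly: zero sample spread, no blue
patients, and point accuracy equal to classical thresholded accuracy.

### The sensitivity sweep

`sensitivity_sweep()` retrains one fresh model per cell of the
$\sigma_{pr}\times\sigma_{po}$ grid and validates it, recording per-cell
seeds. Two deliberate choices:

* **One shared data split across cells** (fresh seeds only for build,
  training and draws), so per-patient quantities are comparable across the
  grid.
* **Full-batch training inside cells.** $\sigma_{po}$ is a posterior
  *initialization* scale; under long minibatch optimization the posterior
  forgets its initialization and the sweep's control parameter becomes
  meaningless. Full-batch steps over the fixed epoch budget bound each
  parameter's movement, so the initialization scale remains visible in the
  predictive spread — which is the phenomenon the sweep exists to measure.
  With that regime, the per-patient predictive standard deviation at
  $\sigma_{po} = 0.1$ sits below its $\sigma_{po} = 2.0$ counterpart for
  essentially every patient.

Cell failures are caught and recorded, and the sweep continues; the
command-line sweep additionally skips cells already present in its output
file, making interrupted grids resumable.

## 3. The synthetic cohort generator

The generator emulates the *schema* of a diabetic heart-failure EHR table:
ten features (four binary, six real) with marginals fixed once in
realistic clinical ranges — age $\sim N(61, 12)$ years, ejection fraction
$\sim N(38, 12)$ percent, creatinine phosphokinase log-normal with median
≈ 245 U/L, serum creatinine log-normal with median ≈ 1.2 mg/dL, serum
sodium $\sim N(136.6, 4.4)$ mEq/L, platelets $\sim N(2.63, 0.97)\times
10^5/\mu L$, prevalences 65/35/32/43% for sex, hypertension, smoking,
anaemia — and explicit dependency rules for the targets:

* $HF \sim \mathrm{Bernoulli}(\mathrm{logit}^{-1}(9.5 - 0.25\,EF))$.
  The negative ejection-fraction coefficient encodes that reduced EF marks
  systolic heart failure; the magnitude was fixed from a generator-only
  calculation so that the Bayes accuracy of the rule (≈ 0.83) comfortably
  supports the learnability levels the tests assert — a weaker slope would
  make those levels unattainable by *any* model.
* $time \sim \mathrm{round}(\max(0,\; 10 - 3.5\,HF - 1.2\,SC + N(0,2)))$
  months, then discretized to TL (0–1 → 0, 2 → 1, 3–4 → 2, ≥5 → 3; the
  2–4-month band spans two classes and the even split is the
  minimal-assumption reading, configurable via `breaks`). The intercept
  keeps truncation at zero below ~1%, so regressing the synthesized times
  on their stated predictors recovers the coefficients within sampling
  error — the generator ships its ground truth with the data for exactly
  this check.

A second, fitted mode (`synthesize_from()`) implements sequential-
regression synthesis in the style of population-synthesis tools: each
variable is drawn from a linear (real) or logistic (binary) model fitted on
the base table given the previously generated variables. Bases under 20
rows are refused as unstable.

What the generator does *not* emulate: measurement error structure, missing
data, longitudinal correlation, site effects, or any claim of clinical
realism. Passing tests on these cohorts certify the machinery — gradients,
statistics, reproducibility, the uncertainty mechanics — not medical
performance on real records. Real heart-failure tables can be loaded with
`read_cohort()`, which accepts the public dataset's long column names, an
optional days→months divisor (the public field is follow-up days), and an
optional EF-threshold rule for deriving the HF label — flagged as an
interpretation, since EF-thresholding makes EF partially encode the label.

## 4. Data hygiene

The 80/20 split is seeded and exhaustive; the min–max scaler and SMOTE see
training rows only, and test values outside the training range deliberately
map outside [0, 1] (no clipping) so leakage cannot hide. SMOTE interpolates
$x + u(x_{nn} - x)$ with $u \sim U(0,1)$ among the $k = 5$ nearest
same-class neighbours, balancing the *composite* (HF, TL) label — the only
order-independent way to serve both targets; singleton classes raise an
error that names the duplication escape hatch rather than silently
duplicating.

## 5. Problem sizes and numerical conventions

The shipped experiments use 1000-patient cohorts (5000 for coefficient
recovery), 300–400 epoch fits, $N = 1000$ validation draws and a
$3\times2$ sweep grid — sizes chosen so a complete run finishes in about a
minute on one core while keeping every statistic comfortably away from its
assertion boundary. Checkpoints serialize all layer parameters to JSON at
full floating-point precision; frozen logic blocks round-trip bit-exactly,
and a reloaded model reproduces in-memory predictions to ~1e-15. All
randomness flows from one user seed through a documented fan-out
(`derive_seed(seed, stage)`), so each pipeline stage is independently
reproducible and sweep cells are order-independent.

## 6. Known limitations

* With $\sigma_{po}$ at its default of 1.0 the fully variational `bnn`
  marginalizes over wide weight noise; its mean predictions compress toward
  the centre of the output range and the binary task can destabilize —
  consistent with the reported sensitivity of HF precision to the posterior
  scale. Informative point predictions want $\sigma_{po} \lesssim 0.1$.
* The dense baseline at learning rate 0.08 occasionally collapses to a
  constant (dead ReLU trunk) for unlucky initialization seeds.
* Gates are fixed a priori: there is no learned gate selection, no
  aggregative operators beyond AND/OR/NOT/NOR, and no automatic formula
  simplification.
* The ordinal task is regression-with-rounding, not a proportional-odds
  model; class distances are assumed uniform.
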