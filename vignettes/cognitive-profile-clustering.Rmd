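---
title: "Methods: factor mixture models and a conditional Gaussian-mixture VAE for cognitive profiles"
author: "cogmix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: factor mixture models and a conditional Gaussian-mixture VAE for cognitive profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of the models it implements, the
judgment calls made where the design was genuinely open, and what the
synthetic experiments do and do not demonstrate.

## The data model

A participant contributes 54 item responses across six subtests and an
age in years. Ages are grouped into left-closed bins $[0,8)$, $[8,12)$,
$[12,100)$; the centered bin index $c \in \{-1,0,+1\}$ is the covariate
throughout, so $c = 0$ is the middle bin and a "one-unit increase in
binned age" means moving up one bin. Binary items are 0/1; the three
visuospatial scores live in $[0,1]$; the working-memory span score is a
nonnegative continuous value.

## Track 1: factor mixture models

### Model family

All variants share class-invariant item parameters: thresholds
$\tau_j$ and loadings $\lambda_j$ (binary items use a logistic link;
continuous items are Gaussian with mean $\tau_j + \lambda_j'\eta$ and
residual variance $\sigma_j^2$). The variants differ in the within-class
factor distribution:

* **FMM-1** (latent class factor analysis): $\Psi_k = 0$, so the factor
  is degenerate at the class mean $\alpha_k$ and the within-class
  likelihood is evaluated at a point — no integration.
* **FMM-2** (mixture factor analysis): $\Psi_k$ free per class; the
  factor is integrated out by Gauss–Hermite quadrature (21 nodes for one
  factor, 9 per dimension for two or three, 2000 seeded Monte-Carlo
  draws beyond). A class whose $\Psi_k$ collapses below $10^{-9}$ is
  evaluated as an exact point mass — the correct $\Psi \to 0$ limit —
  rather than through a vanishing quadrature grid.
* **FA**: one class, standard-normal factors; the factor-count baseline.
* **LCA**: class-conditional independent Bernoulli/Gaussian responses;
  the class-count baseline.

Class membership follows a multinomial-logistic model on $c$ with the
last class as reference, updated by Newton's method with step halving in
the M-step; coefficients are capped at $\pm 15$ under separation, with a
warning.

The link for binary items is logistic rather than probit: it gives
closed-form gradients and matches the logistic concomitant model. The
choice is a package convention, not an empirical claim.

### EM details

The linear predictor takes only one value per (class, quadrature node)
cell, so the E-step and all measurement M-steps operate on cell-level
sufficient statistics ($\sum_i w_{i\mathrm{cell}}$,
$\sum_i w_{i\mathrm{cell}} x_{ij}$, and the square for continuous
items). Item updates are per-item Newton steps with step halving
(guaranteed ascent, parameters boxed at $\pm 12$ on the logit scale);
continuous items have a closed-form weighted least-squares update with
residual variances floored at $10^{-4}$. Class means are updated by BFGS
(degenerate variant) or by posterior node moments (free variant). Every
sub-step ascends the expected complete-data objective, so the observed
log-likelihood is monotone up to floating-point noise; the fit records
its per-iteration history and the tests assert no decrease beyond
$10^{-8}$.

Convergence uses relative log-likelihood change (default $10^{-6}$, max
500 iterations) over a default of 10 restarts (k-means initialization
plus random perturbation). Two warm starts supplement the cold
restarts:

* the degenerate variant starts additionally from a rank-1 SVD
  reduction of the LCA class profiles on the link scale — cold
  coordinate EM otherwise crawls into visibly suboptimal fits;
* the free variant starts additionally from the constrained fit at the
  $\Psi = 0$ boundary, which makes the nesting property
  $\ell(\text{FMM-2}) \ge \ell(\text{FMM-1})$ hold exactly rather than
  only for lucky seeds.

### Identification and label order

The likelihood is invariant to affine rescalings of the factor. The
degenerate variant fixes the scale by constraining the
mixture-weighted mean of the class factor means to 0 and their weighted
variance to 1; the free variant anchors the first loading per factor
(skipping the rescale when the anchor loading is within $\pm 0.2$ of
zero, where dividing by it would explode the remaining loadings).
Classes are always relabeled so first-factor means ascend: "class 1" is
the lowest-performing class. Because the convention behind any
externally obtained $\hat\alpha$ values is generally unknown, recovery
tests align the fitted solution onto the generating convention by the
affine map implied by the loadings and thresholds before comparing.

`fit_lca()` constrains continuous-item variances to be equal across
classes by default (the usual latent-profile default; `equal_variances
= FALSE` frees them). This matters for the model ladder: the
generator's softplus transform of the working-memory score makes its
conditional variance class-dependent, and a heteroscedastic LCA can buy
enough likelihood on that single item to overturn the BIC ranking even
when the data really follow a degenerate-factor mixture.

### Model ladder and parameter counts

`model_ladder()` fits the LCA grid, the FA grid, then both mixture
variants over the class × factor grid (optionally truncated at the
baseline optima), and selects the BIC minimum among converged cells.
Parameter counts deduct the identification constraints; the concomitant
model contributes $2(K-1)$ parameters, a covariate-free mixture $K-1$.
`BIC = -2\ell + p\log n$, `AIC = -2\ell + 2p`.

## Track 2: the conditional Gaussian-mixture VAE

The encoder trunk (two blocks of linear → ReLU → batch-norm; depth
configurable) maps concat($x$, one-hot bin) to three heads: mixture
logits (softmax over $K$), and per-component $\mu_k, \log\sigma^2_k$ of
dimension $D$. Sampling uses the reparameterization trick per component;
the final latent code is the $q_y$-weighted sum. The decoder mirrors the
trunk on concat($z$, $c$) with a sigmoid output head; all 54 features
are in $[0,1]$ after the working-memory score is max-normalized (the
reconstruction inverse-transforms it). A linear head is available.

The KL between a mixture posterior and a mixture prior has no closed
form. The package uses the standard mixture bound: the
$q_y$-weighted sum of per-component Gaussian KLs (closed form, per
latent dimension) plus the categorical KL of $q_y$ against a uniform
component prior. This is the single largest modeling judgment in the
deep track. Free bits clamp the *Gaussian* per-dimension KL at the
threshold (the categorical term is not clamped), so
$\mathrm{KL}_{\text{clamped}} \ge D \cdot \text{free\_bits}$ always, and
the total is exactly
$\text{MSE} + \beta(\mathrm{KL}_{\text{clamped}} + \mathrm{KL}_{\text{cat}})$
— both identities are tracked at every optimization step and surfaced in
`fit$diagnostics`.

Training: Adam with (coupled) weight decay, global-norm gradient
clipping applied to the raw gradients, an 80/20 validation split
stratified by age bin, a reduce-on-plateau scheduler (factor 0.5,
patience 5 — unstated upstream, chosen as the common default), and
best-validation checkpointing. The validation pass reuses one fixed
noise draw for the whole run so that epoch-to-epoch validation losses
compare models rather than draws; without this, checkpoint selection on
small validation sets tracked sampling noise. Non-finite losses abort
with a diagnostic rather than continuing. `membership()` and
`latent_embedding()` are deterministic (posterior means, no sampling;
argmax ties break to the lowest index).

`cgmvae_search()` is a seeded random search over latent dimension
$[4, 64]$, components $[2, 15]$, log-uniform learning rate
$[10^{-4}, 10^{-2}]$ and free bits $[0.01, 0.2]$, scored by best
validation loss, with the winner refit on the full data. Everything —
initialization, split, shuffling, sampling — derives from the config
seed, so a fit is a pure function of (data, config) on one machine.

## Cluster quality and profiling

Validity indices use Euclidean distance throughout. Silhouette assigns
singleton clusters a width of 0; Calinski–Harabasz returns an infinity
sentinel when the within-cluster scatter is zero, as does Davies–Bouldin
and Xie–Beni for coincident centroids. Xie–Beni uses fuzzifier $m = 2$
and membership-weighted centroids so the index is model-agnostic
(externally supplied centroids are accepted). Partition entropy uses the
natural log, so its ceiling is $\ln K$. The mixture-model solution is
scored in its posterior expected factor-score space; the VAE in its
deterministic embedding space.

Z-score profiles are computed per item on the raw feature scale —
cluster mean minus global mean over the global sample SD ($n-1$) —
because that is the scale on which profiles are interpreted;
zero-variance items get $z = 0$ with a flag. Narrative bands
(slight/moderate/severe at $|z|$ 0.2/0.5/1.0) are presentation only.
The reporting filter keeps clusters with $n \ge 10$ (inclusive) in the
interpretation tables while retaining all counts.

## The synthetic generator

The generator is the package's stand-in for cohort data and defines
the conditions under which everything is tested:

* Ages: a three-component normal mixture (means 6.5/10/13.5 years, SD 1)
  truncated to [4, 16]. Component weights are calibrated so the implied
  bin probabilities equal the target composition 670/821/1079 of
  2570 — solving a small linear system, because truncated components
  spill mass across the bin edges.
* Two-class mode: class from the multinomial-logistic model at the
  default coefficients ($\gamma_0 = -0.048$, $\gamma_1 = -0.963$),
  binary items Bernoulli at
  $\mathrm{logit}^{-1}(\tau_j + \lambda_j \alpha_k)$ with
  $\alpha = (-1.451, 0.657)$; the six anchored loadings are assigned to
  their items and the remaining loadings are drawn once from
  $U(0.30, 0.70)$ (thresholds $N(0, 0.5^2)$) under a fixed internal seed
  and frozen as package defaults.
* Continuous items: the noisy linear predictor (residual SD 0.3, a
  plausible measurement-noise level for scores on this scale) passed
  through a logistic squash (visuospatial, guaranteeing $[0,1]$) or a
  softplus (working memory, guaranteeing $\ge 0$). Noise inside the
  transform keeps the range guarantees but makes conditional variances
  class-dependent — a deliberate, documented mismatch with the fitted
  homoscedastic Gaussian measurement model.
* Profile mode: $G$ discrete profiles, each a 54-vector of link-scale
  offsets on a common baseline, with mixing weights optionally varying
  by age bin (e.g. 0.44/0.48/0.54 to emulate a cluster whose prevalence
  grows with age).

What the generator does **not** emulate: item-level dependence beyond a
single factor (testlets), the adaptive stopping rule of the
working-memory task (the score is drawn directly), response styles,
missingness, and any real-data idiosyncrasy. Passing tests therefore
demonstrate correctness of the algorithms under their assumed data
model and graceful behaviour under the two built-in mismatches
(transformed continuous scales; multi-profile data for a two-class
model) — not performance on real cohort data, whose headline fit
statistics are data-dependent and out of scope.

## Problem sizes used by the tests and the acceptance script

Chosen as the package's own desk-scale study conditions: parameter
recovery at $n = 2500$ over three seeds (class means within $\pm 0.15$
after alignment, proportions within $\pm 0.03$, age slope within
$\pm 0.15$); model-selection consistency at $n = 600$ over ten seeds on
the {1–3} classes × {1–2} factors grid with two restarts (expected win
rate ≥ 9/10 for the degenerate two-class one-factor cell); CGMVAE sanity
at $n = 2000$, hidden 64, $D = 8$, 30 epochs, $K = 4$ over five seeds
(adjusted Rand index ≥ 0.5 in at least three) plus one $K = 10$ run.
The acceptance script reruns the same pipeline from a single seed and
writes its numbers as JSON.

## Known limitations

* FMM-3/FMM-4 (class-specific measurement parameters), standard errors
  and bootstrap likelihood-ratio tests are not implemented.
* The free-covariance EM updates class moments on the current quadrature
  grid; its monotonicity is exact only up to the grid's re-centering,
  which is why the strict monotonicity guarantee is asserted for the
  degenerate variant and LCA.
* The VAE trains on one CPU in base R; at the reference scale (hidden
  201, latent 58, $K = 10$) an epoch over a few thousand rows takes
  seconds, but GPU-scale workloads are out of scope.
* With $K = 2$ and one factor, a degenerate-factor mixture and a binary
  LCA are near-equivalent in fit; the BIC preference rests on the
  parsimony of the shared measurement structure and the concomitant
  model, and only grows with $K$.
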