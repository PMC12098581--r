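# cogmix

Two-track clustering of mixed-type cognitive item-response data with an
age covariate, for psychometricians comparing a model-based and a deep
latent-variable view of the same battery.

The data are responses of children and adolescents (ages 4–16) to a
54-item cognitive battery spanning six subtests — logical reasoning (15
binary items), visuospatial attention (3 continuous scores in [0, 1]),
motion perception (5 binary), phonological awareness (13 binary), verbal
comprehension (17 binary) and a working-memory backward span (1
nonnegative continuous score) — plus the participant's age, binned into
[0, 8), [8, 12) and [12, 100) and entered as a centered code
c ∈ {−1, 0, +1}.

## The two tracks

**Factor mixture models.** Responses follow a one-(or multi-)factor
measurement model with K latent classes: for binary item j,

    P(x_ij = 1 | class k) = logit⁻¹(τ_j + λ_j' η),

with thresholds τ and loadings Λ invariant across classes. In the
degenerate-factor variant (FMM-1 / latent class factor analysis) the
within-class factor covariance Ψ is fixed at zero, so η = α_k and classes
differ only in factor mean; the free-covariance variant (FMM-2 / mixture
factor analysis) estimates Ψ_k per class, and the factor is integrated
out by Gauss–Hermite quadrature. Class membership depends on the binned
age code through a multinomial-logistic concomitant model,
log P(k)/P(K) = γ₀ₖ + γ₁ₖ c, updated inside the EM M-step. A model
ladder (`model_ladder()`) fits LCA and factor-analysis baselines and
both mixture variants over a class × factor grid and selects by BIC,
with AIC reported alongside.

**Conditional Gaussian-mixture VAE.** An encoder maps concat(x, c) to
mixture probabilities q(y|x, c) (softmax over K components) and
per-component Gaussian parameters μ_k(x, c), log σ²_k(x, c); latent
samples z_k = μ_k + σ_k ⊙ ε are aggregated as z = Σ_k q_k z_k and decoded
together with c. The prior is a learnable Gaussian mixture (μ_prior,k,
logvar_prior,k). Training minimizes

    L = MSE(x, x̂) + β · ( Σ_d max(KL_d, free_bits) + KL(q_y ‖ uniform) ),

with Adam (weight decay, global-norm gradient clipping), a
reduce-on-plateau scheduler and best-validation checkpointing. The whole
network runs on a small reverse-mode autodiff tape in base R — no deep
learning framework required. Defaults are the tuned values the package ships
(hidden 201, latent 58, K = 10, β = 0.051,
free bits 0.048, lr 9.68e−4, weight decay 4e−5, clip 0.644).

Both solutions are scored with silhouette, Calinski–Harabasz and
Davies–Bouldin indices in their own latent spaces, the fuzzy membership
matrix additionally with Xie–Beni, the fuzzy partition coefficient and
partition entropy, and clusters are interpreted by per-item z-scores
against global statistics with an n ≥ 10 reporting filter.

A synthetic generator (`simulate_fmm1()`, `simulate_profiles()`)
reproduces the battery's schema, the trimodal age distribution (bin
composition calibrated to 670/821/1079 of 2570), and either the
two-class measurement structure of the default generating truth
(α = (−1.451, 0.657), γ = (−0.048, −0.963), six anchored loadings)
or a bank of discrete response profiles with age-varying prevalence, so
every stage is testable without access to cohort data.

## Worked example

```r
library(cogmix)

sim <- simulate_fmm1(1200, seed = 42)          # two-class truth + ages
fit <- fit_fmm(sim, fmm_spec(K = 2, F = 1), restarts = 3, seed = 1)
summary(fit)
#> FMM1, K = 2, F = 1
#> logLik -33514.903  BIC 67838.07  AIC 67257.81
#> class proportions: 44.8%, 55.2%
#> class 1 vs 2: intercept -0.058, age slope -1.068 (OR 0.344)
```

Class 1 is always the lower-performing class (classes are relabeled so
factor means ascend). The age slope is the log-odds change of being in
class 1 rather than class 2 per unit of the centered age code; its odds
ratio of 0.344 here means older children are roughly a third as likely
to fall in the low-performing class, recovering the generating
coefficient −0.963 up to sampling error. Cluster quality in the model's
factor-score space:

```r
quality_report(predict(fit, type = "factor_score"),
               labels = predict(fit, type = "class"),
               U = fit$responsibilities, space = "factor scores")
#> cluster quality (factor scores space; n = 1200, K = 2)
#>   silhouette            1.0000
#>   Davies-Bouldin        0.0000
#>   partition coeff.      1.0000
#>   partition entropy     0.0000
```

On synthetic data at the generating truth the posterior collapses to two
crisp points, so the indices sit at their ideal limits — sharper than on
real data, where the same contrast (near-1 silhouette, near-0
Davies–Bouldin for the two-class model) still holds.

The deep track on multi-profile data:

```r
bank <- default_profile_bank(4, separation = 3)
simp <- simulate_profiles(2000, bank, seed = 1)
cfg  <- cgmvae_config(hidden_dim = 64, latent_dim = 8, n_components = 4,
                      epochs = 30, batch_size = 128, seed = 1)
vae  <- cgmvae(simp, cfg)
table(predict(vae, type = "class"), simp$profile)  # ~pure columns
cluster_feature_zscores(simp, predict(vae, type = "class"),
                        bin = simp$bin)            # z-score profiles
```

`run_compare()` chains the whole comparison (simulate → ladder → CGMVAE →
quality → profiles) from a `compare_config()` or a YAML file and writes
per-stage CSV/JSON artifacts.

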