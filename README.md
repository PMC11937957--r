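# ajgm — adaptive joint graphical models for heterogeneous gene networks

Gene co-expression networks are usually estimated under the assumption that
all samples come from one population. Real expression data — single-cell
RNA-seq in particular — mix unknown subtypes whose networks share a common
backbone but differ in important edges. `ajgm` addresses both problems at
once: it clusters the samples into `K` latent subtypes *and* estimates one
sparse Gaussian graphical model per subtype, together with an *overall
network* fitted to the pooled samples that pulls genuinely shared edges into
every subtype network. It is aimed at statisticians and computational
biologists analyzing heterogeneous bulk or single-cell expression matrices
(samples × genes, log scale).

## The model

Samples follow a Gaussian mixture
`p(x) = Σ_k π_k N(x | μ_k, Ω_k⁻¹)`, where the off-diagonal support of each
precision matrix `Ω_k` is subtype `k`'s network; overall samples `X′`
(by default `X` itself) follow `N(μ_X, Ω_X⁻¹)`. All parameters maximize the
penalized log-likelihood with the adaptive fused penalty

```
P(Θ) = λ₁ ( Σ_{i≠j} Σ_k |θᵢⱼ⁽ᵏ⁾| + Σ_{i≠j} |θᵢⱼ⁽ˣ⁾| )
     + λ₂ Σ_{i≠j} Σ_{k<K} wᵢⱼ⁽ᵏ'ᵏ⁺¹⁾ |θᵢⱼ⁽ᵏ⁾ − θᵢⱼ⁽ᵏ⁺¹⁾|
     + λ₃ Σ_{i≠j} fᵢⱼ wᵢⱼ⁽ᴷ'ˣ⁾ |θᵢⱼ⁽ᴷ⁾ − θᵢⱼ⁽ˣ⁾|,      λ₃ > λ₂,
```

with data-driven weights `w = 1/|θ_a − θ_b|^γ` (large where two networks
already agree, so agreeing entries fuse exactly) and a consensus factor `f`
that applies the full `λ₃` only where all subtypes agree within a threshold
`tre`. Estimation is EM: closed-form updates for `π, μ`, and a consensus-ADMM
update for all K+1 precision matrices whose entrywise subproblem — a
(K+1)-chain weighted fused lasso — is solved exactly. Dropout zeros can be
re-imputed each iteration from the conditional subtype Gaussian, and `K` and
the penalties can be chosen by BIC. Details and design rationale are in the
vignette (`vignettes/adaptive-joint-graphical-models.Rmd`).

## Worked example

Simulate two subtypes over 30 genes (block-structured truth: dense / circle /
star / empty 10×10 modules, 30% of blocks shared), fit with `K = 2`, and
score against the generating truth:

```r
library(ajgm)

cfg <- simulation_config(p = 30, K = 2, nk = 150, seed = 7)
sim <- simulate_ajgm_data(cfg)
fit <- ajgm_fit(sim$data, K = 2,
                cfg = penalty_config(lambda1 = 2, lambda2 = 0.5, lambda3 = 1),
                seed = 1)
print(fit)
#> <ajgm_fit> K = 2, converged after 3 EM iteration(s)
#>   cluster sizes: 150, 150
#>   edges per subtype network: 57, 69
#>   overall network edges: 73
unlist(score_fit(fit, sim$truth, sim$labels))
#>        FPR        TPR         F1        ARI
#> 0.09983719 0.92142857 0.50448521 1.00000000
```

The fit recovers the sample partition perfectly (ARI = 1) and finds 92% of
true edges; the F1 reflects false positives near the edge-calling threshold
at this sample size — raising `edge_threshold` trades recall for precision.
`write_networks()` exports per-network TSV edge lists, a JSON summary and the
cluster assignments; `blockwise_metrics()` splits performance into shared
(public) versus subtype-specific blocks.

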