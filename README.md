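# markernet

Marker-gene discovery by seed-guided network propagation, with penalized
classification and survival stratification.

## The problem

Some disease phenotypes — the motivating case is the neuroendocrine
phenotype of castration-resistant prostate cancer — are clinically defined
by a handful of established marker genes (AR, KLK3, CHGA, SYP, NCAM1,
ENO2) that are individually unreliable, while published expression-based
marker sets barely overlap between cohorts. markernet is for computational
biologists who want to combine differential expression from several
cohorts with protein–protein interaction (PPI) topology to obtain a more
robust ranked candidate list, distill it into a fixed-size marker panel,
and use the panel's probability score for sample classification,
single-cell annotation, and survival stratification.

## The method

Two random walks on the PPI network. First, prior knowledge diffuses from
the seed genes *S*: the guidance value of each gene is the stationary
distribution of a walk restarting uniformly on *S* with probability
β = 1/(1+γ) (flow rate γ = 1 ⇒ β = 0.5),

> g = β·u_S + (1−β)·Wᵀg.

Second, a guided walk restarts (probability α = 0.5) at the
differentially expressed genes, with restart mass proportional to their
averaged |log₂FC| across cohorts (DEGs at strict FDR < 0.05 and
|log₂FC| > 1), and otherwise steps from u to a neighbor v with probability
proportional to edge confidence times guidance,

> P(u→v) = c(u,v)·g(v) / Σ_{v′∈N(u)} c(u,v′)·g(v′),   s = (1−α)·Pᵀs + α·r.

The stationary mass s(v) ranks genes by how strongly expression evidence
and seed-anchored network proximity agree. The top-k candidates
(k chosen by repeated cross-validated AUPRC of an elastic-net logistic
model, with a one-standard-error economy rule) form the marker panel; the
fitted model's case probability is the marker score. Downstream, scores
stratify survival via Kaplan–Meier curves, log-rank tests, and a Cox model
stratified by pathological grade (Gleason 6 → low, 7 → intermediate,
8–10 → high).

A synthetic-data module generates PPI-like networks with a planted,
densified disease module, two-cohort expression with planted effects,
sparse single-cell counts with planted QC violators, and survival times
with a planted hazard coefficient — so every stage is testable against a
known truth.

## Worked example

```r
library(markernet)

sim     <- make_network(n_genes = 2000, module_size = 50, rng_seed = 1)
cohorts <- make_cohorts(sim$truth, rng_seed = 2)        # 2 x (60 case + 60 ctrl)
de      <- lapply(cohorts, differential_test)
degs    <- lapply(de, filter_degs)                       # FDR < 0.05, |lfc| > 1
w       <- build_weights(de, degs, sim$network$nodes)
g       <- compute_guidance(sim$network, sim$truth$seed_genes)
prop    <- guided_stationary(sim$network, g, w)
prop
#> Propagation result: 2000 genes; 50 support genes; 25 iterations (converged)
#> Top genes: G000919, G000105, G001991, G000313, G001773

top50 <- rank_candidates(prop, 50)
sum(top50 %in% sim$truth$module_genes)
#> [1] 50          # all top-50 candidates lie in the planted 50-gene module

pooled <- do.call(cbind, lapply(cohorts, function(co) co$values))
labels <- unlist(lapply(cohorts, function(co) co$labels))
sp  <- split_train_test(labels, train_frac = 0.75, rng_seed = 3)
sel <- select_k(rank_candidates(prop, 100), pooled[, sp$train],
                labels[sp$train], k_grid = c(10, 20, 30, 40),
                folds = 5, repeats = 2, rng_seed = 4)
sel
#> Panel-size selection ( 1se rule): chosen k = 10
#>   k auprc_mean auprc_se       lambda
#>  10          1        0 0.0004341882
#>  20          1        0 0.0006334265
#>  30          1        0 0.0007644144
#>  40          1        0 0.0007673133

model  <- fit_elastic_logistic(t(pooled[top50[1:sel$chosen_k], sp$train]),
                               labels[sp$train], folds = 5, repeats = 2,
                               rng_seed = 5)
auprc(predict_score(model, pooled[, sp$test]), labels[sp$test])
#> [1] 1
```

The planted effect (|log₂FC| = 2 against noise SD 0.25) is deliberately
strong: differential expression recovers exactly the 50 module genes in
each cohort, propagation returns the module as the top of the ranking, the
cross-validated AUPRC saturates at 1 from k = 10 onward (so the economy
rule picks the smallest panel), and the held-out AUPRC is 1. On noisier
real data these numbers drop; the point of the example is that every stage
is exact and checkable against the planted truth.

`run_pipeline(pipeline_config())` executes the same six stages end to end
into a run directory with a manifest; `inst/scripts/markernet.R` wraps it
for the shell.

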