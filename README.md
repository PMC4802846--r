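# geqtl — decoupled group-wise and individual eQTL mapping

`geqtl` is an R package for expression quantitative trait locus (eQTL)
mapping that models **individual** SNP–gene effects and **group-wise**
effects (a set of SNPs jointly regulating a set of genes, as in a pathway)
as separate components, while correcting for hidden confounders.  For a
genotype matrix *X* (K SNPs × H samples, coded 0/1/2) and an expression
matrix *Z* (N genes × H samples), it fits

```
Z = L + (B A + C) X + E
```

by minimizing

```
|| Z − L − (BA + C) X ||²_F + ρ ||L||* + α ||A||₁ + β ||B||₁ + γ pen(C)
```

where `C` (N × K) holds individual associations, the rank-M product `B A`
routes SNP signal through M latent group factors, `L` absorbs low-rank
confounding variation under a nuclear-norm penalty, and `pen(C)` is an
ℓ1 penalty (`geqtl`), an ℓ1 penalty restricted to a correlation-screening
mask (`geqtl_plus`), or a closed-form ridge on the mask support
(`geqtl_ridge`).  The total association matrix is `B A + C`.

The package also provides

* Lasso and low-rank-plus-sparse (LORS-style) baselines
  (`fitLasso()`, `fitLors()`);
* automatic selection of the number of group-wise associations M from the
  singular-value gap of `(Z − L − C X) Xᵀ (X Xᵀ)⁻¹`, iterated to
  stability (`inferM()`, `iterateM()`);
* permutation-based FDR estimation (`permutationFDR()`);
* a simulation generator with block group-wise structure, a cis diagonal,
  latent confounders and SNR control (`simulateEQTL()`, `calibratePhi()`);
* partial-ROC and cross-study reproducibility metrics (`rocCurve()`,
  `topAssocOverlap()`, `hotspotOverlap()`);
* TSV input/output and a command-line front end
  (`inst/scripts/geqtl.R` with subcommands `simulate`, `fit`, `select-m`,
  `evaluate`, `fdr`).

See the methods vignette (`vignettes/geqtl-methods.Rmd`) for the model,
the optimization scheme, the M-selection rule and the generator's
assumptions and limitations.

## Worked example

```r
library(geqtl)

## the reference simulation design: 100 SNPs x 100 genes x 100 samples,
## four group blocks (10, 15, 20, 25 wide) + cis diagonal, phi = tau = 0.1
sim <- simulateEQTL(seed = 1)
sim
#> SimulatedEQTL: 100 SNPs x 100 genes x 100 samples, 4 group blocks + cis diagonal
#>   phi=0.1 tau=0.1 J=10, realized SNR = 5.558

## select M automatically, fitting the model along the way
sel <- iterateM(sim@X, sim@Z,
                options = fitOptions(maxSweeps = 20, tol = 1e-5,
                                     innerMaxIter = 50))
sel$diagnostics
#> RankDiagnostics: chosen M = 4 (stable, 2 iterations)
#>   leading singular values: 2.815 2.495 1.995 1.552 0.6182 0.6044 0.5977 0.5904
```

The first inference round sees the J = 10 confounder factors as apparent
group structure (history `13 -> 4 -> 4`); once the fitted `L` absorbs
them, the four true blocks stand out — note the gap after the fourth
singular value — and the choice stabilizes at M = 4.

```r
fit <- sel$model
fit
#> GeQTLModel (variant 'geqtl')
#>   100 genes x 100 SNPs, M = 4 group-wise associations
#>   penalties: alpha=0.215 beta=0.215 gamma=0.429 rho=2
#>   nonzero: A 98, B 135, C 30; rank(L) = 9
#>   20 sweeps, objective 43.4434 (not converged)

## ranking quality against ground truth, FPR restricted to [0, 0.1]
rocCurve(assocMatrix(fit), truthSupport(sim))
#> RocResult: 3381 points, partial AUC 0.10000 on FPR in [0, 0.1]

la <- fitLasso(sim@X, sim@Z, eta = defaultPenalties(sim@X, sim@Z)$eta)
rocCurve(assocMatrix(la), truthSupport(sim))
#> RocResult: 672 points, partial AUC 0.04287 on FPR in [0, 0.1]
```

At this noise level the decoupled model recovers the full partial area
(0.1 = perfect within the cap) while the Lasso, which cannot pool
group-wise signal or discount confounders, reaches 0.043.  The strongest
individual associations are the cis diagonal cells:

```r
head(associationTable(fit), 5)
#>   gene_id snp_id weight_total weight_individual weight_groupwise
#> 1  gene76  snp76    0.5417378         0.5417378                0
#> 2  gene83  snp83    0.4915262         0.4915262                0
#> 3  gene75  snp75    0.4646013         0.4646013                0
#> 4  gene85  snp85    0.4091473         0.4091473                0
#> 5 gene100 snp100    0.3974570         0.3974570                0
```

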