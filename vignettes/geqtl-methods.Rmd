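---
title: "Decoupled group-wise and individual eQTL mapping with geqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoupled group-wise and individual eQTL mapping with geqtl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geqtl)
```

## The model

An eQTL study measures, for each of $H$ samples, $K$ SNP genotypes (coded
0/1/2 by minor-allele count) and $N$ continuous expression traits, giving a
genotype matrix $X \in \mathbb{R}^{K \times H}$ and an expression matrix
$Z \in \mathbb{R}^{N \times H}$.  Classical single-pair tests, and sparse
multi-task regressions such as the Lasso, treat every SNP–gene link as an
independent coefficient.  Two biological facts argue against that: sets of
SNPs (for instance a locus regulating a pathway) jointly influence sets of
co-regulated genes, and unobserved confounders (batch, environment) induce
structured expression variation that masks or mimics genetic signal.

`geqtl` decouples the association matrix into an individual part and a
low-rank group-wise part, while absorbing confounding into a
nuclear-norm-penalized term:

$$
Z \;=\; L \;+\; (B A + C)\,X \;+\; E,
$$

where

* $C \in \mathbb{R}^{N \times K}$ carries **individual** SNP–gene effects;
* $A \in \mathbb{R}^{M \times K}$ and $B \in \mathbb{R}^{N \times M}$ route
  SNP signal through $M$ latent group factors ($Y = AX$); each factor is one
  **group-wise association** — a SNP set acting on a gene set — and the
  rank-$M$ product $BA$ encodes all of them;
* $L \in \mathbb{R}^{N \times H}$ is a low-rank **confounder** matrix;
* $E$ is Gaussian noise.

The fitted objective is

$$
\min_{A,B,C,L} \;
\|Z - L - (BA + C)X\|_F^2
+ \rho\,\|L\|_* + \alpha\,\|A\|_1 + \beta\,\|B\|_1 + \mathrm{pen}(C),
$$

with $\mathrm{pen}(C) = \gamma \|C\|_1$ for the variants `geqtl` and
`geqtl_plus`, and $\gamma \|C\|_2^2$ for `geqtl_ridge`.  Intercepts are
dropped because both matrices are standardized row-wise as preprocessing.
The total association strength of a pair is the corresponding entry of
$BA + C$ (`assocMatrix()`).

### Standardization convention

Rows are centered and scaled to **unit sum of squares** rather than unit
variance (`standardizeRows()`).  The two conventions differ only by the
factor $\sqrt{H-1}$, but under unit sum of squares the matrix $Z X^\top$ is
*exactly* the matrix of sample gene–SNP correlations, which makes the
correlation-screening step an identity rather than an approximation.  All
penalties quoted below live on this scale.

### The screened variants

`geqtl_plus` restricts the support of $C$ to a mask $R$ computed by
marginal-correlation screening (`screenMask()`): $R_{ij} = 1$ iff
$|r_{ij}| = |(Z X^\top)_{ij}|$ exceeds the correlation threshold obtained
by inverting the two-sided $t$ test with $H-2$ degrees of freedom at the
requested p-value.  We use the standard relation
$t = r\sqrt{H-2}/\sqrt{1-r^2}$; the default p-value is 0.01 and is
recorded in the returned `ScreeningMask`.  `geqtl_ridge` uses the same
mask but replaces the $\ell_1$ penalty on $C$ with a ridge penalty, for
which each row of $C$ has a closed-form minimizer on its admitted columns:
with $D = Z - L - BAX$ and $P_i$ the selector of row $i$'s admitted
columns,

$$
c_i \leftarrow d_i X^\top P_i
\left(P_i^\top X X^\top P_i + \gamma I\right)^{-1} P_i^\top ,
$$

an $l_i \times l_i$ solve per distinct mask row (`updateCRidge()`,
verified in the tests against an independent augmented-least-squares
solver).

## Optimization

Blocks are updated in the order $C, L, A, B$ each sweep.

* **$L$**: exact minimizer by singular-value thresholding.  Because the
  objective carries $\|\cdot\|_F^2$ (not $\tfrac12\|\cdot\|_F^2$), the
  proximal threshold is $\rho/2$: `L <- svt(Z - (BA + C)X, rho / 2)`.
* **$A$, $B$, $C$ ($\ell_1$)**: accelerated proximal gradient (FISTA) with
  an exact Lipschitz step $1/(2\sigma_{\max}(B)^2\sigma_{\max}(X)^2)$ and a
  best-iterate safeguard: the accepted iterate is the one with the lowest
  subproblem objective seen, so each block update — and hence the overall
  objective — is monotone to machine precision.  Masked entries are simply
  projected to zero after each proximal step (the constraint set is a
  coordinate subspace).
* **$C$ (ridge)**: the closed form above, an exact block minimizer.

Initialization is deterministic.  $C$ starts from a light Lasso fit whose
penalty is floored at twice the Bonferroni-level correlation threshold
($p = 0.01$ over all $N K$ pairs): by the Lasso stationarity condition
this keeps every pair without a clearly significant marginal correlation
at zero, so the initial $C$ captures strong individual (cis-like) signals
while leaving group-wise structure in the residual.  An unpenalized
initial $C$ would absorb the entire association matrix and starve the
factors — visible as a rank-0 $BA$ on noiseless realizable data.  $(A, B)$
are then the top-$M$ SVD factors of the regularized least-squares group
estimate (below), with row signs fixed so each row of $A$ has a positive
largest-magnitude entry; $L$ starts at zero.

Convergence is declared when the relative objective change per sweep drops
below `tol` (default $10^{-6}$); `maxSweeps` (default 50) bounds the work,
and exhausting it marks the model `converged = FALSE` rather than raising
an error.

### Default penalties

When not supplied, penalties come from `defaultPenalties()`: the $\ell_1$
levels are fractions of the universal correlation-noise threshold
$2\sqrt{2\log(NK)/H}$ (under pure noise, standardized-scale marginal
correlations are $\mathcal{N}(0, 1/H)$), and $\rho$ places the SVT level
$\rho/2$ at the Marchenko–Pastur-style noise edge
$(\sqrt{N}+\sqrt{H})/\sqrt{H}$ of a pure-noise residual, so $L$ only
absorbs directions stronger than what noise alone produces.  These are
sensible starting points at the default simulation scale;
cross-validation over a grid (`cvGeQTL()`, splitting samples into folds
and scoring held-out prediction error of $(BA + C)X$ — $L$ is
sample-specific and excluded from prediction) refines them when accuracy
matters more than speed.

## Choosing the number of group-wise associations

Distinct group-wise associations cannot share their SNP set or gene set
(they would merge into one), so $A$ and $B$ have full rank $M$ and
$M = \mathrm{rank}(BA)$.  The least-squares estimate of the group product
given $C$ and $L$ is

$$
\widehat{BA} = (Z - L - C X)\, X^\top (X X^\top)^{-1},
$$

and $M$ can be read off its singular-value profile.  Two numerical points
matter:

* **Regularized inverse.**  Centered rows make $X X^\top$ rank deficient
  whenever $K \ge H$, and its near-null directions amplify noise into
  large spurious singular values (on the reference simulation the top
  spurious value is an order of magnitude above the true block values).
  `inferM()` therefore adds `ridge` (default 0.5) times the mean
  eigenvalue to the diagonal.  The filter factors
  $\sigma^2/(\sigma^2 + \varepsilon)$ shrink all singular values
  monotonically and preserve rank and gap structure exactly — on
  noiseless data the recovered rank is exact for any ridge (this is a
  property test in the suite).
* **Gap rule.**  "Large and significantly greater than the next" is made
  operational as: choose the $k \le$ `cap` maximizing $s_k / s_{k+1}$
  among candidates with $s_k > \delta\, s_1$ (default $\delta = 0.05$;
  the floor keeps noise-floor ratios out of the running).  The choice is
  flagged unstable when the winning ratio is below `minRatio` (default 2),
  which is what a pure-noise profile produces.

`iterateM()` wraps this in the refinement loop: initialize $C$ by Lasso
(same Bonferroni-floored penalty as above), infer $M$, fit the full model
at that $M$, re-infer from the fitted $(L, C)$, and repeat until $M$ is
stable.  The first round sees the confounders as group structure (with
$J = 10$ hidden factors it typically reports $M \approx 14$ on the
reference design); once the fitted $L$ absorbs them, the second round
drops to the true number of blocks and stabilizes.  An oscillation
between two values returns the smaller with `stable = FALSE`.

## The simulation generator

`simulateEQTL()` reproduces the reference simulation design used
throughout the tests: $K = N = H = 100$; four group-wise association
blocks of increasing scale ($10 \times 10$, $15\times15$, $20\times20$,
$25\times25$ — consecutive, disjoint index ranges) plus a cis diagonal,
all with association strength 1; expression generated as
$Z = \beta X + \Xi + E$ with noise $E_{ij} \sim \mathcal{N}(0, \phi)$,
$\phi = 0.1$, and confounder rows
$\Xi_{j*} \sim \mathcal{N}(0, \tau F F^\top)$ with a single
$H \times J$ standard-normal loading matrix $F$ shared across genes,
$\tau = 0.1$, $J = 10$.  The realized signal-to-noise ratio is
$\mathrm{SNR} = \sqrt{\mathrm{Var}(\beta X) / \mathrm{Var}(\Xi + E)}$ over
matrix entries, and `calibratePhi()` solves for the $\phi$ that hits a
requested SNR for a given design.

Genotypes are synthesized as independent $\mathrm{Binomial}(2,
\mathrm{maf})$ minor-allele counts with per-SNP allele frequencies drawn
uniformly from `mafRange` (default 0.1–0.5) — a deliberate simplification
of real panels, which it does **not** emulate in two respects worth
keeping in mind:

* **No linkage disequilibrium.**  Real genotype panels (e.g. a yeast
  segregant cross) carry strong local correlation, which concentrates a
  block's signal into every member SNP.  With independent SNPs the same
  nominal SNR is a much harder detection problem: at a calibrated
  $\mathrm{SNR} = 0.13$ the largest block's singular value in the
  standardized expression matrix is roughly $0.3$ against a noise edge of
  about $2$, i.e. below the spectral detection threshold, and *every*
  method's partial AUC sits near the chance line, with group pooling
  contributing only a small edge.  The method ordering (geqtl and
  geqtl_plus above Lasso, ridge close behind) is unambiguous from
  $\mathrm{SNR} \gtrsim 0.7$ on this generator.  Passing tests at low SNR
  therefore demonstrate the ordering, not field-realistic power.
* **No allele-frequency spectrum or population structure.**

Each dataset stores its full decomposition ($\beta$, blocks, $F$, $\Xi$,
$E$, every parameter and the seed), so ground-truth support for ROC
labeling is available without re-derivation, and `writeSimulation()`
exports everything as TSV with a provenance sidecar.

## Evaluation metrics

`rocCurve()` sweeps a threshold over $|BA + C|$ against the true support
(blocks and cis diagonal both count as positives), with tied weights
entering the call set together, and reports the trapezoidal partial AUC on
FPR $\in [0, 0.1]$ — the region that matters when tolerated false-positive
rates are small.  The area is reported unnormalized together with the cap.
A weight matrix with a single distinct value yields a single operating
point and is scored as $\mathrm{cap} \times \mathrm{TPR}$.  The
implementation is tested for exact agreement with a quadratic-time
brute-force enumeration.

Cross-study reproducibility uses two overlap fractions: the shared
proportion of the top-$T$ (gene, SNP) pairs of two ranked association
lists (`topAssocOverlap()`), and the shared proportion of the top-$T$
regulatory hotspots — SNPs ranked by how many genes they are associated
with — with ties at the boundary broken by stable SNP-id order
(`hotspotOverlap()`).

`permutationFDR()` estimates the false discovery rate of a thresholded
weight matrix by refitting on column-permuted genotypes (breaking all
SNP–gene links while preserving each matrix's internal correlation
structure): $\widehat{\mathrm{FDR}}(t)$ is the mean permuted count of
weights above $t$ over the observed count, clipped to $[0,1]$ and
monotonized to be non-increasing in $t$.  Fifty permutations is the
conventional choice; the tests use ten.

## Problem sizes and numerical choices

The default test and acceptance runs use the reference $100^3$ design (or
smaller) with `maxSweeps = 20`, `tol = 1e-5` and `innerMaxIter = 50`,
which reproduces the selection and ordering results in seconds per
dataset; production fits can afford the stricter defaults.  Degenerate
inputs are handled explicitly: constant rows abort standardization with
the offending row named; an empty mask row yields a zero coefficient row;
`svt` with $\lambda = 0$ is the identity and with $\lambda \ge d_1$ the
zero matrix; ties at exactly $\lambda$ shrink to zero.  All randomness is
seed-controlled and the caller's RNG state is restored.

## Limitations

* The generator's independent SNPs make nominal SNR values incomparable
  with LD-structured panels (see above).
* $M$ selection relies on a visible singular-value gap; overlapping or
  near-collinear group associations can merge.
* Hyperparameter defaults are calibrated for standardized inputs at
  roughly the reference design scale; very different $N/H$ aspect ratios
  warrant cross-validation.
* No genomic-position awareness: cis windows, LD pruning and
  position-based hotspot definitions are out of scope.
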