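## Synthetic eQTL data: block group-wise associations, a cis diagonal,
## low-rank confounding and Gaussian noise.

.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(seed)
    return(expr)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Synthesize a genotype matrix
#'
#' Draws each SNP independently as Binomial(2, maf) minor-allele counts with
#' its own allele frequency sampled uniformly from `mafRange`.  For `H >= 2`
#' monomorphic rows are redrawn (bounded retries) so that downstream
#' standardization is well defined.
#'
#' @param K number of SNPs
#' @param H number of samples
#' @param mafRange length-2 numeric within (0, 0.5], allele-frequency range
#' @param seed optional RNG seed (restores the caller's RNG state)
#' @return a raw [GenotypeMatrix-class] with entries in 0/1/2
#' @export
makeGenotypes <- function(K, H, mafRange = c(0.1, 0.5), seed = NULL) {
  stopifnot(K >= 1, H >= 1)
  if (length(mafRange) != 2L || mafRange[1] <= 0 || mafRange[2] > 0.5 ||
      mafRange[1] > mafRange[2])
    stop("'mafRange' must be within (0, 0.5]")
  .withSeed(seed, {
    maf <- stats::runif(K, mafRange[1], mafRange[2])
    vals <- matrix(stats::rbinom(K * H, 2L, rep(maf, times = H)), K, H)
    if (H >= 2L) {
      for (tries in 1:50) {
        mono <- apply(vals, 1L, function(r) all(r == r[1L]))
        if (!any(mono)) break
        vals[mono, ] <- matrix(
          stats::rbinom(sum(mono) * H, 2L, rep(maf[mono], times = H)),
          sum(mono), H)
      }
    }
    GenotypeMatrix(vals)
  })
}

.defaultGroupSizes <- function(nGroups, K, N) {
  if (nGroups == 0L) return(list())
  ## "different scales": sizes proportional to 2,3,...; for the default
  ## 100 x 100 grid with 4 groups this gives 10, 15, 20, 25
  w <- seq(2L, nGroups + 1L)
  f <- 0.7 * min(K, N) / sum(w)
  sizes <- pmax(1L, round(f * w))
  lapply(sizes, function(s) c(s, s))
}

#' Lay out the ground-truth coefficient matrix
#'
#' Builds the N x K coefficient matrix `beta` with value `strength` on each
#' group block (a SNP index set crossed with a gene index set) and, when
#' `cisDiagonal` is on, on the diagonal cells representing individual cis
#' signals.  Blocks are placed at consecutive, pairwise-disjoint positions.
#'
#' @param K,N grid dimensions (SNPs, genes)
#' @param nGroups number of group-wise association blocks
#' @param groupSizes list of length-2 vectors `c(snpExtent, geneExtent)`;
#'   `NULL` uses blocks of increasing scale (10, 15, 20, 25 on the default
#'   100 x 100 grid)
#' @param strength coefficient value for all true associations
#' @param cisDiagonal logical, add the individual cis diagonal
#' @return a [SimTruth-class] with `beta` and `blocks` populated (confounder
#'   and noise components are filled in by [makeExpression()])
#' @export
makeTruth <- function(K, N, nGroups = 4L, groupSizes = NULL, strength = 1,
                      cisDiagonal = TRUE) {
  if (is.null(groupSizes)) groupSizes <- .defaultGroupSizes(nGroups, K, N)
  if (length(groupSizes) != nGroups)
    stop("length(groupSizes) must equal nGroups")
  beta <- matrix(0, N, K)
  blocks <- list()
  sAt <- 1L; gAt <- 1L
  for (b in seq_along(groupSizes)) {
    ext <- groupSizes[[b]]
    snps <- seq.int(sAt, length.out = ext[1])
    genes <- seq.int(gAt, length.out = ext[2])
    if (max(snps) > K || max(genes) > N)
      stop("group blocks do not fit in the ", N, " x ", K, " grid")
    beta[genes, snps] <- strength
    blocks[[b]] <- list(snps = snps, genes = genes)
    sAt <- max(snps) + 1L; gAt <- max(genes) + 1L
  }
  if (cisDiagonal) {
    d <- seq_len(min(N, K))
    beta[cbind(d, d)] <- strength
  }
  new("SimTruth", beta = beta, blocks = blocks,
      F = matrix(0, 0, 0), Xi = matrix(0, 0, 0), E = matrix(0, 0, 0))
}

#' Generate expression traits from genotypes and ground truth
#'
#' Simulates `Z = beta %*% X + Xi + E`, where each row of the confounder
#' effect `Xi` is drawn independently from `N(0, tau * F F^T)` with a single
#' H x J loading matrix `F` (standard-normal entries) shared across genes,
#' and `E` has i.i.d. `N(0, phi)` entries.
#'
#' @param X raw [GenotypeMatrix-class] (or plain matrix)
#' @param truth a [SimTruth-class] from [makeTruth()]
#' @param phi Gaussian noise variance
#' @param tau confounder scale
#' @param J number of hidden factors
#' @param seed optional RNG seed
#' @return list with elements `Z` (an [ExpressionMatrix-class]) and `truth`
#'   (the input truth with `F`, `Xi`, `E` filled in)
#' @export
makeExpression <- function(X, truth, phi = 0.1, tau = 0.1, J = 10L,
                           seed = NULL) {
  Xv <- if (is(X, "GenotypeMatrix")) as.matrix(X) else as.matrix(X)
  stopifnot(phi >= 0, tau >= 0, J >= 0)
  beta <- truth@beta
  if (ncol(beta) != nrow(Xv))
    stop("truth and genotype dimensions disagree")
  N <- nrow(beta); H <- ncol(Xv)
  .withSeed(seed, {
    F <- matrix(stats::rnorm(H * J), H, J)
    Xi <- if (tau > 0 && J > 0)
      sqrt(tau) * tcrossprod(matrix(stats::rnorm(N * J), N, J), F)
    else matrix(0, N, H)
    E <- if (phi > 0) matrix(stats::rnorm(N * H, sd = sqrt(phi)), N, H)
    else matrix(0, N, H)
    Z <- beta %*% Xv + Xi + E
    rownames(Z) <- paste0("gene", seq_len(N))
    colnames(Z) <- colnames(Xv)
    list(Z = ExpressionMatrix(Z),
         truth = new("SimTruth", beta = beta, blocks = truth@blocks,
                     F = F, Xi = Xi, E = E))
  })
}

#' Realized signal-to-noise ratio of a simulated dataset
#'
#' `SNR = sqrt(Var(beta X) / Var(Xi + E))`, with variances taken over all
#' matrix entries of the realized components.
#'
#' @param object a [SimTruth-class] (then `X` is required) or a
#'   [SimulatedEQTL-class]
#' @param X raw genotype matrix paired with the truth
#' @param ... unused
#' @return positive scalar (0 when `beta` is all zero)
#' @name snr
NULL

#' @rdname snr
setMethod("snr", "SimTruth", function(object, X, ...) {
  Xv <- if (is(X, "GenotypeMatrix")) as.matrix(X) else as.matrix(X)
  if (length(object@Xi) == 0L)
    stop("truth has no realized noise components; run makeExpression first")
  noise <- stats::var(as.vector(object@Xi + object@E))
  if (noise <= 0) stop("zero noise variance; SNR undefined")
  sqrt(stats::var(as.vector(object@beta %*% Xv)) / noise)
})

#' @rdname snr
setMethod("snr", "SimulatedEQTL", function(object, ...) {
  snr(object@truth, object@X)
})

#' Simulate a complete eQTL dataset
#'
#' One-call generator combining [makeGenotypes()], [makeTruth()] and
#' [makeExpression()].  Defaults reproduce the reference simulation design:
#' a 100 SNP x 100 gene x 100 sample grid with four group-wise association
#' blocks of increasing scale plus a cis diagonal, association strength 1,
#' noise variance `phi = 0.1`, confounder scale `tau = 0.1` and `J = 10`
#' hidden factors.
#'
#' @param K,N,H numbers of SNPs, genes and samples
#' @param nGroups,groupSizes,strength,cisDiagonal see [makeTruth()]
#' @param phi,tau,J see [makeExpression()]
#' @param mafRange see [makeGenotypes()]
#' @param seed RNG seed controlling the whole dataset
#' @return a [SimulatedEQTL-class]
#' @examples
#' sim <- simulateEQTL(K = 30, N = 30, H = 40, seed = 1)
#' snr(sim)
#' @export
simulateEQTL <- function(K = 100L, N = 100L, H = 100L, nGroups = 4L,
                         groupSizes = NULL, strength = 1, phi = 0.1,
                         tau = 0.1, J = 10L, cisDiagonal = TRUE,
                         mafRange = c(0.1, 0.5), seed = NULL) {
  .withSeed(seed, {
    X <- makeGenotypes(K, H, mafRange)
    truth0 <- makeTruth(K, N, nGroups, groupSizes, strength, cisDiagonal)
    ze <- makeExpression(X, truth0, phi = phi, tau = tau, J = J)
    new("SimulatedEQTL", X = X, Z = ze$Z, truth = ze$truth,
        config = list(K = K, N = N, H = H, nGroups = nGroups,
                      groupSizes = groupSizes, strength = strength,
                      phi = phi, tau = tau, J = J,
                      cisDiagonal = cisDiagonal, mafRange = mafRange,
                      seed = seed))
  })
}

#' Find the noise variance that yields a target SNR
#'
#' Generates the signal and confounder components for the given design and
#' solves for the noise variance `phi` such that the expected
#' signal-to-noise ratio `sqrt(Var(beta X) / (Var(Xi) + phi))` equals
#' `targetSnr`.  This mirrors the way different noise levels are used to
#' sweep SNR in the simulation study.
#'
#' @param targetSnr requested SNR (> 0)
#' @param ... design arguments passed to [simulateEQTL()] (all but `phi`)
#' @param seed RNG seed for the calibration draw
#' @return the calibrated noise variance `phi`
#' @export
calibratePhi <- function(targetSnr, ..., seed = NULL) {
  stopifnot(targetSnr > 0)
  sim <- simulateEQTL(..., phi = 0, seed = seed)
  S <- stats::var(as.vector(sim@truth@beta %*% as.matrix(sim@X)))
  V <- stats::var(as.vector(sim@truth@Xi))
  phi <- S / targetSnr^2 - V
  if (phi <= 0)
    stop("target SNR too high for this design: confounder variance alone ",
         "exceeds the required noise level")
  phi
}

#' Ground-truth support of a simulation
#'
#' @param truth a [SimTruth-class] or [SimulatedEQTL-class]
#' @return logical N x K matrix, `TRUE` where `beta` is nonzero
#' @export
truthSupport <- function(truth) {
  if (is(truth, "SimulatedEQTL")) truth <- truth@truth
  truth@beta != 0
}
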