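#' Fitting options for the alternating solvers
#'
#' @param maxSweeps maximum number of coordinate sweeps over the blocks
#' @param tol relative objective-change convergence tolerance per sweep
#' @param innerMaxIter iteration cap for each proximal-gradient subproblem
#' @param seed optional RNG seed (initialization is deterministic, so this
#'   only matters for user-supplied stochastic extensions)
#' @param verbose print per-sweep objective values
#' @return a named list of options
#' @export
fitOptions <- function(maxSweeps = 50L, tol = 1e-6, innerMaxIter = 100L,
                       seed = NULL, verbose = FALSE) {
  stopifnot(maxSweeps >= 1L, tol > 0, innerMaxIter >= 1L)
  list(maxSweeps = as.integer(maxSweeps), tol = tol,
       innerMaxIter = as.integer(innerMaxIter), seed = seed,
       verbose = isTRUE(verbose))
}

#' Fit the Lasso baseline
#'
#' Minimizes `||Z - W X||_F^2 + eta ||W||_1` over the N x K coefficient
#' matrix W (inputs standardized row-wise first).
#'
#' @param X genotype input ([GenotypeMatrix-class] or matrix)
#' @param Z expression input ([ExpressionMatrix-class] or matrix)
#' @param eta nonnegative l1 penalty
#' @param options see [fitOptions()]; `innerMaxIter` bounds the proximal
#'   gradient iterations
#' @return a [BaselineModel-class] with variant `"lasso"`
#' @export
fitLasso <- function(X, Z, eta, options = fitOptions()) {
  if (eta < 0) stop("'eta' must be nonnegative")
  Xs <- .stdValues(X); Zs <- .stdValues(Z)
  .checkAligned(Xs, Zs)
  obj0 <- sum(Zs * Zs)
  W <- .l1Solve(Zs, NULL, Xs, eta, init = matrix(0, nrow(Zs), nrow(Xs)),
                maxIter = options$innerMaxIter)
  dimnames(W) <- list(rownames(Zs), rownames(Xs))
  obj1 <- sum((Zs - W %*% Xs)^2) + eta * sum(abs(W))
  new("BaselineModel", W = W, L = NULL, variant = "lasso",
      hyperparams = list(eta = eta), objectiveTrace = c(obj0, obj1),
      converged = TRUE)
}

#' Fit the low-rank-plus-sparse (LORS-style) baseline
#'
#' Minimizes `||Z - W X - L||_F^2 + eta ||W||_1 + rho ||L||_*` by
#' alternating a proximal-gradient update of W with the exact
#' singular-value-thresholding update `L <- svt(Z - W X, rho / 2)`.
#'
#' @inheritParams fitLasso
#' @param rho nonnegative nuclear-norm penalty on the confounder matrix L
#' @return a [BaselineModel-class] with variant `"lors"`; `converged` is
#'   `FALSE` when `maxSweeps` was exhausted before the tolerance was met
#' @export
fitLors <- function(X, Z, eta, rho, options = fitOptions()) {
  if (eta < 0 || rho < 0) stop("'eta' and 'rho' must be nonnegative")
  Xs <- .stdValues(X); Zs <- .stdValues(Z)
  .checkAligned(Xs, Zs)
  N <- nrow(Zs); K <- nrow(Xs); H <- ncol(Xs)
  W <- matrix(0, N, K); L <- matrix(0, N, H)
  objFn <- function(W, L)
    sum((Zs - W %*% Xs - L)^2) + eta * sum(abs(W)) + rho * .nuclearNorm(L)
  trace <- objFn(W, L)
  converged <- FALSE
  for (sweep in seq_len(options$maxSweeps)) {
    W <- .l1Solve(Zs - L, NULL, Xs, eta, init = W,
                  maxIter = options$innerMaxIter)
    trace <- c(trace, objFn(W, L))
    L <- svt(Zs - W %*% Xs, rho / 2)
    obj <- objFn(W, L)
    trace <- c(trace, obj)
    prev <- trace[length(trace) - 2L]
    if (options$verbose)
      message(sprintf("lors sweep %d: objective %.8g", sweep, obj))
    if (abs(prev - obj) <= options$tol * max(1, abs(prev))) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("LORS did not reach tolerance within maxSweeps")
  dimnames(W) <- list(rownames(Zs), rownames(Xs))
  new("BaselineModel", W = W, L = L, variant = "lors",
      hyperparams = list(eta = eta, rho = rho), objectiveTrace = trace,
      converged = converged)
}

.checkAligned <- function(Xs, Zs) {
  if (ncol(Xs) != ncol(Zs))
    stop("genotype and expression matrices have different sample counts")
  cx <- colnames(Xs); cz <- colnames(Zs)
  if (!is.null(cx) && !is.null(cz) && !identical(cx, cz))
    stop("sample identifiers of X and Z do not match in order")
}

#' Correlation screening of candidate individual associations
#'
#' With rows of X and Z standardized to zero mean and unit sum of squares,
#' `r = abs(Z %*% t(X))` equals the matrix of absolute sample gene-SNP
#' correlations.  The requested two-sided p-value is converted into a
#' correlation threshold through the t distribution with `H - 2` degrees of
#' freedom (`t = r sqrt(H - 2) / sqrt(1 - r^2)`), and the mask admits the
#' pairs whose `|r|` exceed it.
#'
#' @inheritParams fitLasso
#' @param pvalue two-sided significance level in (0, 1)
#' @return a [ScreeningMask-class]
#' @export
screenMask <- function(X, Z, pvalue = 0.01) {
  if (pvalue <= 0 || pvalue >= 1) stop("'pvalue' must be in (0, 1)")
  H <- ncol(if (is(X, "GenotypeMatrix")) as.matrix(X) else as.matrix(X))
  if (H <= 3L) stop("screening needs H > 3 samples for the t threshold")
  Xs <- .stdValues(X); Zs <- .stdValues(Z)
  .checkAligned(Xs, Zs)
  tq <- stats::qt(1 - pvalue / 2, df = H - 2)
  thr <- tq / sqrt(H - 2 + tq^2)
  r <- abs(tcrossprod(Zs, Xs))
  R <- (r > thr) * 1
  dimnames(R) <- list(rownames(Zs), rownames(Xs))
  new("ScreeningMask", R = R, thresholdR = thr, pvalue = pvalue)
}
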