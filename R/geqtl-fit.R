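#' Exact confounder update by singular-value thresholding
#'
#' Block minimizer of the penalized objective in L for fixed (A, B, C):
#' `L <- svt(Z - (B A + C) X, rho / 2)`.  The factor 1/2 maps the
#' `||.||^2 + rho ||L||_*` objective onto the proximal form
#' `0.5 ||.||^2 + lam ||L||_*` solved by [svt()].
#'
#' @inheritParams geqtlLoss
#' @param rho nonnegative nuclear-norm penalty
#' @return the updated N x H matrix L
#' @export
updateL <- function(Z, A, B, C, X, rho) {
  svt(as.matrix(Z) - (B %*% A + C) %*% as.matrix(X), rho / 2)
}

#' Column-selection projector for a mask row
#'
#' Builds the K x l selector whose t-th column has a single 1 at the
#' position of the t-th set bit of `maskRow`, so `t(P) %*% P` is the l x l
#' identity and `P %*% t(P)` is the diagonal mask.
#'
#' @param maskRow binary (0/1 or logical) vector of length K
#' @return a K x l matrix, where l is the number of set bits
#' @export
buildProjector <- function(maskRow) {
  idx <- which(maskRow != 0)
  P <- matrix(0, length(maskRow), length(idx))
  if (length(idx)) P[cbind(idx, seq_along(idx))] <- 1
  P
}

#' Closed-form ridge update of the individual associations
#'
#' Row-wise exact minimizer of `||D - C X||_F^2 + gamma ||C||_2^2` subject
#' to the support constraint that `C[i, j]` may be nonzero only where
#' `R[i, j] = 1`, with `D = Z - L - B A X`:
#' `c_i <- d_i X^T P_i (P_i^T X X^T P_i + gamma I)^{-1} P_i^T`,
#' where `P_i` selects the admitted columns (the inverse is of the reduced
#' size l_i x l_i).
#'
#' @inheritParams geqtlLoss
#' @param R binary N x K mask (matrix or [ScreeningMask-class])
#' @param gamma positive ridge penalty
#' @return the updated N x K matrix C, zero outside the mask support
#' @export
updateCRidge <- function(Z, L, A, B, X, R, gamma) {
  if (is(R, "ScreeningMask")) R <- R@R
  Z <- as.matrix(Z); X <- as.matrix(X)
  if (gamma < 0) stop("'gamma' must be nonnegative")
  D <- Z - L - B %*% A %*% X
  N <- nrow(Z); K <- nrow(X)
  stopifnot(all(dim(R) == c(N, K)))
  XXt <- tcrossprod(X)
  C <- matrix(0, N, K)
  ## group genes sharing a mask row so each reduced Gram is factored once
  key <- apply(R != 0, 1L, paste, collapse = "")
  for (rows in split(seq_len(N), key)) {
    idx <- which(R[rows[1L], ] != 0)
    if (!length(idx)) next
    G <- XXt[idx, idx, drop = FALSE]
    diag(G) <- diag(G) + gamma
    rhs <- tcrossprod(D[rows, , drop = FALSE], X[idx, , drop = FALSE])
    C[rows, idx] <- t(solve(G, t(rhs)))
  }
  C
}

## least-squares estimate of the group product BA given C and L.
## Standardized rows are centered, so XX^T is rank deficient whenever
## K >= H and near-singular directions amplify noise; `ridge` (relative to
## the mean eigenvalue of XX^T) shrinks those directions.  The tiny default
## only restores invertibility; rank inference uses a substantial value
## (see inferM).
.groupLS <- function(Xs, Zs, L, C, ridge = 1e-8) {
  XXt <- tcrossprod(Xs)
  diag(XXt) <- diag(XXt) + ridge * sum(diag(XXt)) / nrow(XXt)
  resid <- Zs - L - C %*% Xs
  t(solve(XXt, Xs %*% t(resid)))
}

## deterministic (B, A) initialization from the top-M SVD of the
## least-squares group estimate; A-row signs fixed so the largest-magnitude
## entry of each row is positive
.initAB <- function(WLS, M) {
  s <- svd(WLS, nu = M, nv = M)
  d <- sqrt(pmax(s$d[seq_len(M)], 0))
  B <- s$u %*% diag(d, M, M)
  A <- diag(d, M, M) %*% t(s$v)
  for (m in seq_len(M)) {
    j <- which.max(abs(A[m, ]))
    if (A[m, j] < 0) {
      A[m, ] <- -A[m, ]
      B[, m] <- -B[, m]
    }
  }
  list(A = A, B = B)
}

#' Data-driven default penalties
#'
#' Heuristic regularization levels on the standardized (zero-mean, unit
#' sum-of-squares rows) scale: the l1 penalties are set to a fraction of the
#' universal noise threshold `2 sqrt(2 log(N K) / H)` for marginal
#' correlations, and `rho` so that the SVT level `rho / 2` sits at the
#' Marchenko-Pastur-style noise edge `(sqrt(N) + sqrt(H)) / sqrt(H)` of a
#' pure-noise residual.  These are starting points; cross-validation (see
#' [cvGeQTL()]) refines them when accuracy matters more than speed.
#'
#' @inheritParams fitLasso
#' @return named list with elements alpha, beta, gamma, rho and eta
#' @export
defaultPenalties <- function(X, Z) {
  Xs <- .stdValues(X); Zs <- .stdValues(Z)
  N <- nrow(Zs); K <- nrow(Xs); H <- ncol(Xs)
  uni <- 2 * sqrt(2 * log(N * K) / H)
  edge <- (sqrt(N) + sqrt(H)) / sqrt(H)
  list(alpha = 0.25 * uni, beta = 0.25 * uni, gamma = 0.5 * uni,
       rho = edge, eta = 0.5 * uni)
}

#' Fit the decoupled group-wise + individual association model
#'
#' Alternating block minimization of
#' `||Z - L - (B A + C) X||_F^2 + rho ||L||_* + alpha ||A||_1 +
#'  beta ||B||_1 + pen(C)` where `pen(C)` is `gamma ||C||_1` for variants
#' `"geqtl"` and `"geqtl_plus"` and `gamma ||C||_2^2` for `"geqtl_ridge"`.
#' The screened variants restrict the support of C to a
#' [ScreeningMask-class].  Blocks are updated in the order C, L, A, B; the
#' L update is the exact SVT minimizer, the ridge C update is the exact
#' closed form, and the l1 blocks use safeguarded accelerated proximal
#' gradient steps, so the objective is non-increasing after every update.
#'
#' Initialization is deterministic: C from a one-block l1 (or ridge) fit,
#' L = 0, and (A, B) from the top-M SVD of the least-squares group estimate
#' `(Z - C X) X^T (X X^T + eps I)^{-1}`.
#'
#' @inheritParams fitLasso
#' @param M number of group-wise associations (latent factors),
#'   `M <= min(K, N)`; see [inferM()] / [iterateM()] to choose it
#' @param alpha,beta,gamma,rho nonnegative penalties on A, B, C, L; missing
#'   values are filled from [defaultPenalties()]
#' @param variant `"geqtl"` (l1 C, no mask), `"geqtl_plus"` (l1 C restricted
#'   to a correlation-screening mask) or `"geqtl_ridge"` (closed-form ridge
#'   C on the mask support)
#' @param mask a [ScreeningMask-class] (required for the screened variants;
#'   built automatically from `screenPvalue` when omitted)
#' @param screenPvalue p-value used to build the mask when `mask` is missing
#' @return a [GeQTLModel-class]
#' @examples
#' sim <- simulateEQTL(K = 30, N = 30, H = 40, seed = 7)
#' fit <- fitGeQTL(sim@X, sim@Z, M = 4)
#' fit
#' @export
fitGeQTL <- function(X, Z, M, alpha = NULL, beta = NULL, gamma = NULL,
                     rho = NULL,
                     variant = c("geqtl", "geqtl_plus", "geqtl_ridge"),
                     mask = NULL, screenPvalue = 0.01,
                     options = fitOptions()) {
  variant <- match.arg(variant)
  Xs <- .stdValues(X); Zs <- .stdValues(Z)
  .checkAligned(Xs, Zs)
  N <- nrow(Zs); K <- nrow(Xs); H <- ncol(Xs)
  M <- as.integer(M)
  if (M < 1L || M > min(K, N))
    stop("'M' must satisfy 1 <= M <= min(K, N)")
  def <- defaultPenalties(Xs, Zs)
  if (is.null(alpha)) alpha <- def$alpha
  if (is.null(beta)) beta <- def$beta
  if (is.null(gamma)) gamma <- def$gamma
  if (is.null(rho)) rho <- def$rho
  if (min(alpha, beta, gamma, rho) < 0)
    stop("penalties must be nonnegative")
  if (variant == "geqtl_ridge" && gamma <= 0)
    stop("the ridge variant requires gamma > 0")

  if (variant == "geqtl") {
    mask <- NULL
    maskMat <- NULL
  } else {
    if (is.null(mask)) mask <- screenMask(Xs, Zs, pvalue = screenPvalue)
    if (!is(mask, "ScreeningMask")) {
      maskMat <- as.matrix(mask) != 0
      mask <- new("ScreeningMask", R = (maskMat) * 1,
                  thresholdR = 0, pvalue = NA_real_)
    }
    maskMat <- mask@R != 0
    stopifnot(all(dim(maskMat) == c(N, K)))
  }

  inner <- options$innerMaxIter
  updateC <- function(A, B, L, C) {
    Tc <- Zs - L - B %*% A %*% Xs
    if (variant == "geqtl_ridge")
      updateCRidge(Zs, L, A, B, Xs, maskMat * 1, gamma)
    else
      .l1Solve(Tc, NULL, Xs, gamma, init = C, mask = maskMat,
               maxIter = inner)
  }

  ## --- deterministic initialization.  The initial C comes from a light
  ## Lasso fit whose penalty is floored at twice the Bonferroni-level
  ## correlation threshold: it captures clearly-significant individual
  ## signals but leaves group-wise structure in the residual for the
  ## (A, B) factor initialization (an unpenalized C would absorb the whole
  ## association matrix and starve the factors).
  L <- matrix(0, N, H)
  tq <- stats::qt(1 - 0.01 / (N * K) / 2, df = max(H - 2, 1))
  lamInit <- max(gamma, 2 * tq / sqrt(H - 2 + tq^2))
  C <- if (variant == "geqtl_ridge")
    updateCRidge(Zs, L, matrix(0, 1L, K), matrix(0, N, 1L), Xs,
                 maskMat * 1, gamma)
  else
    .l1Solve(Zs, NULL, Xs, lamInit, init = matrix(0, N, K),
             mask = maskMat, maxIter = inner)
  ab <- .initAB(.groupLS(Xs, Zs, L, C, ridge = 0.5), M)
  A <- ab$A; B <- ab$B

  objFn <- function(A, B, C, L)
    .objectiveValue(Zs, Xs, A, B, C, L, alpha, beta, gamma, rho, variant)
  trace <- objFn(A, B, C, L)
  names(trace) <- "init"
  converged <- FALSE
  sweeps <- 0L
  for (sweep in seq_len(options$maxSweeps)) {
    prevSweep <- trace[length(trace)]
    C <- updateC(A, B, L, C)
    trace <- .pushObj(trace, objFn(A, B, C, L), "C")
    L <- svt(Zs - (B %*% A + C) %*% Xs, rho / 2)
    trace <- .pushObj(trace, objFn(A, B, C, L), "L")
    A <- .l1Solve(Zs - L - C %*% Xs, B, Xs, alpha, init = A,
                  maxIter = inner)
    trace <- .pushObj(trace, objFn(A, B, C, L), "A")
    B <- .l1Solve(Zs - L - C %*% Xs, NULL, A %*% Xs, beta, init = B,
                  maxIter = inner)
    trace <- .pushObj(trace, objFn(A, B, C, L), "B")
    sweeps <- sweep
    obj <- trace[length(trace)]
    if (options$verbose)
      message(sprintf("%s sweep %d: objective %.8g", variant, sweep, obj))
    if (abs(prevSweep - obj) <= options$tol * max(1, abs(prevSweep))) {
      converged <- TRUE
      break
    }
  }
  dimnames(A) <- list(NULL, rownames(Xs))
  dimnames(B) <- list(rownames(Zs), NULL)
  dimnames(C) <- list(rownames(Zs), rownames(Xs))
  dimnames(L) <- list(rownames(Zs), colnames(Zs))
  ## Class= spelled out: a named 'C' argument would otherwise partially
  ## match new()'s 'Class' formal
  new(Class = "GeQTLModel", A = A, B = B, C = C, L = L, M = M,
      variant = variant,
      hyperparams = list(alpha = alpha, beta = beta, gamma = gamma,
                         rho = rho),
      mask = mask, objectiveTrace = trace, sweeps = sweeps,
      converged = converged)
}

.pushObj <- function(trace, obj, block) {
  prev <- trace[length(trace)]
  if (obj > prev + 1e-9 * max(1, abs(prev)))
    stop(sprintf(
      "objective increased after the %s update (%.10g -> %.10g)",
      block, prev, obj))
  trace <- c(trace, obj)
  names(trace)[length(trace)] <- block
  trace
}

#' Cross-validated penalty selection
#'
#' k-fold cross-validation over a penalty grid, splitting samples; the
#' score is the held-out prediction error `||Z_test - (B A + C) X_test||_F^2`
#' (the confounder matrix L is sample-specific and is not used for
#' prediction).
#'
#' @inheritParams fitGeQTL
#' @param grid data.frame with columns among alpha, beta, gamma, rho; each
#'   row is one candidate setting (missing columns fall back to defaults)
#' @param nFolds number of folds (>= 2)
#' @param seed RNG seed for the fold assignment
#' @return list with `best` (the winning row of `grid`), `scores` (mean CV
#'   error per row) and `fit` (the model refit on all samples at `best`)
#' @export
cvGeQTL <- function(X, Z, M, grid, nFolds = 5L,
                    variant = c("geqtl", "geqtl_plus", "geqtl_ridge"),
                    mask = NULL, screenPvalue = 0.01,
                    options = fitOptions(), seed = NULL) {
  variant <- match.arg(variant)
  Xs <- .stdValues(X); Zs <- .stdValues(Z)
  H <- ncol(Xs)
  stopifnot(nFolds >= 2L, nrow(grid) >= 1L)
  folds <- .withSeed(seed, sample(rep_len(seq_len(nFolds), H)))
  scores <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    err <- 0
    for (f in seq_len(nFolds)) {
      te <- folds == f
      fit <- fitGeQTL(Xs[, !te, drop = FALSE], Zs[, !te, drop = FALSE],
                      M = M,
                      alpha = grid$alpha[g], beta = grid$beta[g],
                      gamma = grid$gamma[g], rho = grid$rho[g],
                      variant = variant, mask = mask,
                      screenPvalue = screenPvalue, options = options)
      pred <- assocMatrix(fit) %*% Xs[, te, drop = FALSE]
      err <- err + sum((Zs[, te, drop = FALSE] - pred)^2)
    }
    scores[g] <- err / nFolds
  }
  best <- which.min(scores)
  fit <- fitGeQTL(Xs, Zs, M = M, alpha = grid$alpha[best],
                  beta = grid$beta[best], gamma = grid$gamma[best],
                  rho = grid$rho[best], variant = variant, mask = mask,
                  screenPvalue = screenPvalue, options = options)
  list(best = grid[best, , drop = FALSE], scores = scores, fit = fit)
}
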