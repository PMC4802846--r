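#' Infer the number of group-wise associations from a singular-value gap
#'
#' Computes the least-squares estimate of the group product
#' `B A = (Z - L - C X) X^T (X X^T)^{-1}` (with a small ridge floor when
#' `X X^T` is rank deficient) and selects M as the index k maximizing the
#' gap ratio `s_k / s_{k+1}` among the leading singular values, requiring
#' `s_k > delta * s_1` so that noise-floor gaps are ignored.
#'
#' @inheritParams fitLasso
#' @param L N x H confounder matrix (default 0)
#' @param C N x K individual-association matrix (default 0)
#' @param cap consider gaps only among the first `min(cap, r - 1)` singular
#'   values
#' @param delta relative magnitude floor: candidates must exceed
#'   `delta * s_1`
#' @param ridge ridge added to `X X^T` relative to its mean eigenvalue.
#'   Standardized rows are centered, so `X X^T` is rank deficient for
#'   `K >= H` and its near-null directions amplify noise into large
#'   spurious singular values; the default (0.5) shrinks them to the scale
#'   of the mean eigenvalue while leaving the rank structure of the signal
#'   intact (shrinkage is monotone in the singular values, so gaps are
#'   preserved)
#' @param minRatio dominance requirement: the selected gap ratio
#'   `s_M / s_{M+1}` must reach this value for the choice to be flagged
#'   `stable`; below it no singular value is "significantly greater" than
#'   the next and the diagnostics report instability
#' @return a [RankDiagnostics-class]; `chosenM = 0` with `stable = FALSE`
#'   when every singular value is below the numerical floor
#' @export
inferM <- function(X, Z, L = NULL, C = NULL, cap = 20L, delta = 0.05,
                   ridge = 0.5, minRatio = 2) {
  Xs <- .stdValues(X); Zs <- .stdValues(Z)
  .checkAligned(Xs, Zs)
  N <- nrow(Zs); K <- nrow(Xs)
  if (is.null(L)) L <- matrix(0, N, ncol(Zs))
  if (is.null(C)) C <- matrix(0, N, K)
  WLS <- .groupLS(Xs, Zs, L, C, ridge = ridge)
  s <- svd(WLS, nu = 0, nv = 0)$d
  floorVal <- 1e-10 * max(s, .Machine$double.eps)
  if (all(s <= floorVal))
    return(new("RankDiagnostics", singularValues = s,
               gapRatios = numeric(0), chosenM = 0L, iterations = 0L,
               stable = FALSE))
  kMax <- min(cap, sum(s > floorVal), length(s) - 1L)
  ratios <- s[seq_len(kMax)] / pmax(s[seq_len(kMax) + 1L], floorVal)
  eligible <- s[seq_len(kMax)] > delta * s[1L]
  if (!any(eligible))
    return(new("RankDiagnostics", singularValues = s, gapRatios = ratios,
               chosenM = 1L, iterations = 0L, stable = FALSE))
  cand <- which(eligible)
  chosen <- cand[which.max(ratios[cand])]
  new("RankDiagnostics", singularValues = s, gapRatios = ratios,
      chosenM = as.integer(chosen), iterations = 0L,
      stable = ratios[chosen] >= minRatio)
}

#' Iteratively refine the number of group-wise associations
#'
#' Implements the stabilization loop for choosing M: initialize C with a
#' Lasso fit, infer M from the singular-value gap, fit the full model at
#' that M, re-infer M from the refit (L, C), and repeat until M is
#' unchanged between consecutive rounds or `maxOuter` is reached.  If the
#' sequence oscillates between two values the smaller is returned with
#' `stable = FALSE`.
#'
#' @inheritParams fitGeQTL
#' @param etaInit l1 penalty of the initializing Lasso fit.  The default is
#'   twice the Bonferroni-corrected correlation threshold (p = 0.01 over
#'   all N*K pairs, via the t map of [screenMask()]): at this level the
#'   Lasso's stationarity condition keeps every pair without a clearly
#'   significant marginal correlation at zero, so the initial C captures
#'   strong individual (cis-like) signals while leaving group-wise
#'   structure in the residual for the rank step to see
#' @param maxOuter maximum outer refinement rounds (>= 1)
#' @param cap,delta,ridge gap-rule knobs, see [inferM()]
#' @param ... further arguments passed to [fitGeQTL()]
#' @return list with elements `M`, `model` (the last [GeQTLModel-class], or
#'   `NULL` when `maxOuter = 1`), `diagnostics` (a
#'   [RankDiagnostics-class]), `stable`, and `history` (the sequence of
#'   inferred M values)
#' @export
iterateM <- function(X, Z, etaInit = NULL, maxOuter = 5L, cap = 20L,
                     delta = 0.05, ridge = 0.5, options = fitOptions(),
                     ...) {
  stopifnot(maxOuter >= 1L)
  Xs <- .stdValues(X); Zs <- .stdValues(Z)
  if (is.null(etaInit)) {
    N <- nrow(Zs); K <- nrow(Xs); H <- ncol(Xs)
    tq <- stats::qt(1 - 0.01 / (N * K) / 2, df = H - 2)
    etaInit <- 2 * tq / sqrt(H - 2 + tq^2)
  }
  C <- assocMatrix(fitLasso(Xs, Zs, eta = etaInit, options = options))
  diag0 <- inferM(Xs, Zs, C = C, cap = cap, delta = delta, ridge = ridge)
  history <- diag0@chosenM
  diagnostics <- diag0
  model <- NULL
  stable <- FALSE
  for (round in seq_len(maxOuter - 1L)) {
    M <- history[length(history)]
    if (M < 1L) break
    model <- fitGeQTL(Xs, Zs, M = M, options = options, ...)
    diagnostics <- inferM(Xs, Zs, L = model@L, C = model@C, cap = cap,
                          delta = delta, ridge = ridge)
    history <- c(history, diagnostics@chosenM)
    n <- length(history)
    if (history[n] == history[n - 1L]) {
      stable <- TRUE
      break
    }
    if (n >= 3L && history[n] == history[n - 2L]) {
      ## oscillation between two values: keep the smaller
      history <- c(history, min(history[n], history[n - 1L]))
      stable <- FALSE
      break
    }
  }
  M <- history[length(history)]
  diagnostics@iterations <- length(history) - 1L
  diagnostics@stable <- stable
  list(M = M, model = model, diagnostics = diagnostics, stable = stable,
       history = history)
}

#' Permutation-based FDR estimation for association weights
#'
#' For each permutation the sample columns of X are shuffled, breaking all
#' SNP-gene links while preserving the internal structure of both matrices;
#' the model is refit and the absolute association weights collected.  The
#' estimated FDR at threshold t is the mean permuted count of weights above
#' t divided by the observed count, clipped to `[0, 1]` and monotonized to
#' be non-increasing in t.
#'
#' @inheritParams fitLasso
#' @param fitFn function `(X, Z) -> N x K weight matrix` (e.g. wrap
#'   [fitGeQTL()] and return [assocMatrix()])
#' @param nPerm number of permutations (>= 1); 50 is the conventional
#'   choice, smaller values keep tests fast
#' @param thresholds numeric thresholds at which to evaluate the FDR;
#'   defaults to a grid of quantiles of the observed nonzero `|weights|`
#' @param seed optional RNG seed for the permutations
#' @return data.frame with columns threshold, observed, expectedNull, fdr
#'   (fdr is `NA` where the observed count is zero)
#' @export
permutationFDR <- function(X, Z, fitFn, nPerm = 50L, thresholds = NULL,
                           seed = NULL) {
  if (!is.function(fitFn)) stop("'fitFn' must be a function(X, Z)")
  nPerm <- as.integer(nPerm)
  if (nPerm < 1L) stop("'nPerm' must be at least 1")
  Xs <- .stdValues(X); Zs <- .stdValues(Z)
  .checkAligned(Xs, Zs)
  H <- ncol(Xs)
  wObs <- abs(fitFn(Xs, Zs))
  if (is.null(thresholds)) {
    nz <- wObs[wObs > 0]
    thresholds <- if (length(nz))
      unique(c(0, stats::quantile(nz, probs = seq(0, 0.99, length.out = 50),
                                  names = FALSE)))
    else 0
  }
  thresholds <- sort(unique(thresholds))
  obsCount <- vapply(thresholds, function(t) sum(wObs > t), numeric(1))
  nullCount <- numeric(length(thresholds))
  .withSeed(seed, {
    for (p in seq_len(nPerm)) {
      Xp <- Xs[, sample.int(H), drop = FALSE]
      colnames(Xp) <- colnames(Xs)
      wp <- abs(fitFn(Xp, Zs))
      nullCount <- nullCount +
        vapply(thresholds, function(t) sum(wp > t), numeric(1))
    }
  })
  expectedNull <- nullCount / nPerm
  fdr <- ifelse(obsCount > 0, pmin(1, pmax(0, expectedNull / obsCount)),
                NA_real_)
  ## non-increasing in t: never report a larger FDR at a stricter threshold
  ok <- !is.na(fdr)
  fdr[ok] <- cummin(fdr[ok])
  data.frame(threshold = thresholds, observed = obsCount,
             expectedNull = expectedNull, fdr = fdr)
}
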