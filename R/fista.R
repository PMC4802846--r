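## Internal proximal-gradient solver for the l1-penalized least-squares
## block subproblems
##
##   min_A  || T - B A X ||_F^2 + lam * ||A||_1,
##
## optionally constrained to a fixed support (mask).  B = NULL means the
## identity, which covers the W, C and B blocks; a general B covers the A
## block.  Accelerated (FISTA) iterations with a best-iterate safeguard: the
## returned matrix never has a larger subproblem objective than `init`, so
## every block update of the alternating scheme is monotone.

.l1Solve <- function(Tmat, B, X, lam, init, mask = NULL,
                     maxIter = 100L, relTol = 1e-10) {
  XXt <- tcrossprod(X)
  if (is.null(B)) {
    G0 <- tcrossprod(Tmat, X)          # T X^T
    lipB <- 1
  } else {
    BtB <- crossprod(B)
    G0 <- crossprod(B, tcrossprod(Tmat, X))   # B^T T X^T
    lipB <- .symSpec(BtB)
  }
  lip <- 2 * lipB * .symSpec(XXt)
  if (lip <= 0) return(init * 0)
  step <- 1 / lip
  c0 <- sum(Tmat * Tmat)

  quadOf <- function(A) {
    ## || T - B A X ||_F^2 expanded; cost O(dim(A)^2-ish)
    AX2 <- if (is.null(B)) A %*% XXt else BtB %*% A %*% XXt
    c0 - 2 * sum(A * G0) + sum(A * AX2)
  }
  objOf <- function(A) quadOf(A) + lam * sum(abs(A))
  gradOf <- function(A) {
    if (is.null(B)) 2 * (A %*% XXt - G0)
    else 2 * (BtB %*% A %*% XXt - G0)
  }
  prox <- function(A, thr) {
    A <- sign(A) * pmax(abs(A) - thr, 0)
    if (!is.null(mask)) A[!mask] <- 0
    A
  }

  Acur <- init
  if (!is.null(mask)) Acur[!mask] <- 0
  best <- Acur
  fBest <- objOf(Acur)
  Y <- Acur
  t <- 1
  fPrev <- fBest
  for (it in seq_len(maxIter)) {
    Anew <- prox(Y - step * gradOf(Y), step * lam)
    f <- objOf(Anew)
    if (f < fBest) { fBest <- f; best <- Anew }
    tNew <- (1 + sqrt(1 + 4 * t^2)) / 2
    Y <- Anew + ((t - 1) / tNew) * (Anew - Acur)
    Acur <- Anew
    t <- tNew
    if (abs(fPrev - f) <= relTol * max(1, abs(fPrev))) break
    fPrev <- f
  }
  best
}

## spectral norm of a symmetric PSD matrix
.symSpec <- function(S) {
  if (nrow(S) == 0L) return(0)
  max(eigen(S, symmetric = TRUE, only.values = TRUE)$values, 0)
}
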