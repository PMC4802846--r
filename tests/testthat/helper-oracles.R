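## Independent oracles used by the tests.  Each deliberately takes a
## different computational route from the package implementation it checks.

## Lasso objective/solution via glmnet coordinate descent (per gene row).
## Our objective ||Z - W X||_F^2 + eta ||W||_1 maps onto glmnet's
## (1/(2n)) ||y - X b||^2 + lambda ||b||_1 with lambda = eta / (2 H).
oracleLasso <- function(Xs, Zs, eta) {
  H <- ncol(Xs)
  W <- t(sapply(seq_len(nrow(Zs)), function(i) {
    fit <- glmnet::glmnet(t(Xs), Zs[i, ], lambda = eta / (2 * H),
                          standardize = FALSE, intercept = FALSE,
                          thresh = 1e-14)
    as.numeric(fit$beta)
  }))
  list(W = W, obj = sum((Zs - W %*% Xs)^2) + eta * sum(abs(W)))
}

## Masked ridge row solved as an augmented ordinary least-squares problem
## by QR (stacking sqrt(gamma) * I under the design), independent of the
## projector closed form.
oracleMaskedRidge <- function(Zmat, Lmat, A, B, Xmat, R, gamma) {
  D <- Zmat - Lmat - B %*% A %*% Xmat
  N <- nrow(Zmat); K <- nrow(Xmat)
  C <- matrix(0, N, K)
  for (i in seq_len(N)) {
    idx <- which(R[i, ] != 0)
    if (!length(idx)) next
    Q <- t(Xmat[idx, , drop = FALSE])            # H x l
    aug <- rbind(Q, sqrt(gamma) * diag(length(idx)))
    rhs <- c(D[i, ], rep(0, length(idx)))
    C[i, idx] <- qr.solve(aug, rhs)
  }
  C
}

## Generic convex solver for the nuclear-norm proximal problem
##   min_S 0.5 ||O - S||_F^2 + lam ||S||_*
## via BFGS on the Huber-smoothed spectral objective (smoothing mu); the
## subgradient of the smoothed nuclear norm is U h'(d) V^T.
oracleNuclearProx <- function(O, lam, mu = 1e-9) {
  n <- nrow(O); p <- ncol(O)
  fn <- function(s) {
    S <- matrix(s, n, p)
    d <- svd(S, nu = 0, nv = 0)$d
    0.5 * sum((O - S)^2) + lam * sum(sqrt(d^2 + mu^2) - mu)
  }
  gr <- function(s) {
    S <- matrix(s, n, p)
    sv <- svd(S)
    g <- (S - O) + lam * sv$u %*% (sv$d / sqrt(sv$d^2 + mu^2) * t(sv$v))
    as.vector(g)
  }
  opt <- stats::optim(as.vector(O), fn, gr, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-16))
  matrix(opt$par, n, p)
}

## Quadratic-time brute-force ROC sweep: one operating point per distinct
## threshold, counted by full scans; same tie and degenerate-case
## conventions as the implementation contract.
oracleRoc <- function(weights, truth, fprCap = 0.1) {
  w <- abs(as.vector(weights)); lab <- as.vector(truth != 0)
  P <- sum(lab); Ng <- sum(!lab)
  thr <- sort(unique(w), decreasing = TRUE)
  fpr <- tpr <- numeric(length(thr))
  for (k in seq_along(thr)) {
    call <- w >= thr[k]
    tpr[k] <- sum(call & lab) / P
    fpr[k] <- sum(call & !lab) / Ng
  }
  if (length(thr) == 1L)
    return(list(fpr = fpr, tpr = tpr, pauc = fprCap * tpr))
  fprA <- c(0, fpr); tprA <- c(0, tpr)
  area <- 0
  for (i in seq_len(length(fprA) - 1L)) {
    x0 <- fprA[i]; x1 <- fprA[i + 1L]
    if (x0 >= fprCap) break
    y0 <- tprA[i]; y1 <- tprA[i + 1L]
    if (x1 > fprCap) {
      y1 <- y0 + (y1 - y0) * (fprCap - x0) / (x1 - x0)
      x1 <- fprCap
    }
    area <- area + (x1 - x0) * (y0 + y1) / 2
  }
  list(fpr = fprA, tpr = tprA, pauc = area)
}

## brute-force elementwise loss for small instances
oracleLoss <- function(Z, L, A, B, C, X) {
  tot <- 0
  W <- B %*% A + C
  for (j in seq_len(nrow(Z))) for (h in seq_len(ncol(Z))) {
    pred <- L[j, h] + sum(W[j, ] * X[, h])
    tot <- tot + (Z[j, h] - pred)^2
  }
  tot
}

randStdInstance <- function(N, K, H, seed) {
  set.seed(seed)
  Xs <- standardizeRows(matrix(rbinom(K * H, 2, runif(K, 0.2, 0.5)), K, H))
  Zs <- standardizeRows(matrix(rnorm(N * H), N, H))
  list(Xs = Xs, Zs = Zs)
}
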