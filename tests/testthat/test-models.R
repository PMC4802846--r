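test_that("lasso baseline recovers least squares at eta = 0 and zeroes out
           beyond the subgradient bound", {
  inst <- randStdInstance(4, 5, 30, seed = 101)
  ols <- fitLasso(inst$Xs, inst$Zs, eta = 0,
                  options = fitOptions(innerMaxIter = 3000))
  Wols <- t(qr.solve(t(inst$Xs), t(inst$Zs)))
  expect_equal(unname(assocMatrix(ols)), Wols, tolerance = 1e-4)

  etaMax <- 2 * max(abs(tcrossprod(inst$Zs, inst$Xs)))
  z <- fitLasso(inst$Xs, inst$Zs, eta = etaMax * 1.001)
  expect_identical(sum(assocMatrix(z) != 0), 0L)
  expect_error(fitLasso(inst$Xs, inst$Zs, eta = -1), "nonnegative")
})

test_that("lasso objective matches the glmnet coordinate-descent oracle", {
  for (seed in c(102, 103)) {
    inst <- randStdInstance(5, 7, 20, seed = seed)
    eta <- 0.3
    fit <- fitLasso(inst$Xs, inst$Zs, eta = eta,
                    options = fitOptions(innerMaxIter = 3000))
    obj <- sum((inst$Zs - assocMatrix(fit) %*% inst$Xs)^2) +
      eta * sum(abs(assocMatrix(fit)))
    orc <- oracleLasso(inst$Xs, inst$Zs, eta)
    expect_equal(obj, orc$obj, tolerance = 1e-6)
  }
})

test_that("LORS collapses to its penalty limits", {
  inst <- randStdInstance(6, 5, 18, seed = 104)
  ## rho huge: L = 0, fit equals plain lasso
  lors <- fitLors(inst$Xs, inst$Zs, eta = 0.2, rho = 1e6)
  expect_identical(sum(confounders(lors) != 0), 0L)
  las <- fitLasso(inst$Xs, inst$Zs, eta = 0.2,
                  options = fitOptions(innerMaxIter = 2000))
  objOf <- function(W) sum((inst$Zs - W %*% inst$Xs)^2) +
    0.2 * sum(abs(W))
  expect_equal(objOf(assocMatrix(lors)), objOf(assocMatrix(las)),
               tolerance = 1e-6)
  expect_equal(assocMatrix(lors), assocMatrix(las), tolerance = 1e-3)

  ## eta huge: W = 0, L is one SVT of Z at rho/2
  etaMax <- 2 * max(abs(tcrossprod(inst$Zs, inst$Xs)))
  lors2 <- fitLors(inst$Xs, inst$Zs, eta = 2 * etaMax, rho = 0.8)
  expect_identical(sum(assocMatrix(lors2) != 0), 0L)
  expect_equal(confounders(lors2), svt(inst$Zs, 0.4), tolerance = 1e-10)

  ## adding L never hurts the (W from lasso, L = 0) objective
  lors3 <- fitLors(inst$Xs, inst$Zs, eta = 0.2, rho = 0.8)
  objLassoOnly <- sum((inst$Zs - assocMatrix(las) %*% inst$Xs)^2) +
    0.2 * sum(abs(assocMatrix(las)))
  expect_lte(tail(objectiveTrace(lors3), 1), objLassoOnly + 1e-10)
})

test_that("screening threshold agrees with per-pair regression p-values", {
  set.seed(105)
  K <- 5; N <- 5; H <- 50
  X <- matrix(rbinom(K * H, 2, 0.4), K, H)
  Z <- matrix(rnorm(N * H), N, H)
  Z[1, ] <- X[2, ] + rnorm(H, sd = 0.4)
  mask <- screenMask(X, Z, pvalue = 0.01)
  pv <- matrix(NA_real_, N, K)
  for (i in 1:N) for (j in 1:K)
    pv[i, j] <- summary(lm(Z[i, ] ~ X[j, ]))$coefficients[2, 4]
  expect_identical(unname(mask@R), (pv < 0.01) * 1)

  ## a gene duplicated from a SNP is always admitted
  Zdup <- rbind(X[1, ], Z[-1, ])
  expect_identical(screenMask(X, Zdup, pvalue = 1e-6)@R[1, 1], 1)

  ## p-value -> 1 admits (essentially) everything
  expect_gt(mean(screenMask(X, Z, pvalue = 0.9999)@R), 0.99)

  expect_error(screenMask(X[, 1:3], Z[, 1:3], 0.01), "H > 3")
  expect_error(screenMask(X, Z, pvalue = 0), "in \\(0, 1\\)")
})

test_that("the mask projector has the selector structure", {
  P <- buildProjector(c(1, 0, 1))
  expect_identical(dim(P), c(3L, 2L))
  expect_equal(crossprod(P), diag(2))
  expect_equal(P %*% t(P), diag(c(1, 0, 1)))
  expect_equal(buildProjector(rep(1, 4)), diag(4))
  expect_identical(dim(buildProjector(c(0, 0))), c(2L, 0L))
})

test_that("confounder update is the exact block minimizer", {
  inst <- randStdInstance(5, 4, 12, seed = 106)
  A <- matrix(rnorm(8), 2, 4); B <- matrix(rnorm(10), 5, 2)
  C <- matrix(rnorm(20), 5, 4)
  ## rho = 0 returns the residual itself
  L0 <- updateL(inst$Zs, A, B, C, inst$Xs, rho = 0)
  expect_equal(L0, inst$Zs - (B %*% A + C) %*% inst$Xs)
  ## rank-0 residual maps to zero
  Zfit <- (B %*% A + C) %*% inst$Xs
  expect_equal(updateL(Zfit, A, B, C, inst$Xs, rho = 0.5),
               matrix(0, 5, 12))
  ## exact minimizer: beats random perturbations of itself
  L <- updateL(inst$Zs, A, B, C, inst$Xs, rho = 1)
  objL <- function(Lc) geqtlLoss(inst$Zs, Lc, A, B, C, inst$Xs) +
    1 * sum(svd(Lc)$d)
  base <- objL(L)
  set.seed(107)
  for (i in 1:10)
    expect_gte(objL(L + matrix(rnorm(60, sd = 0.05), 5, 12)), base)
})

test_that("masked ridge update matches the augmented-QR oracle and honors
           empty rows", {
  set.seed(108)
  for (rep in 1:5) {
    N <- sample(3:6, 1); K <- sample(4:10, 1); H <- sample(8:15, 1)
    Xs <- standardizeRows(matrix(rnorm(K * H), K, H))
    Zs <- standardizeRows(matrix(rnorm(N * H), N, H))
    A <- matrix(rnorm(2 * K), 2, K); B <- matrix(rnorm(N * 2), N, 2)
    L <- matrix(rnorm(N * H, sd = 0.1), N, H)
    R <- matrix(rbinom(N * K, 1, 0.5), N, K)
    R[1, ] <- 0   # empty mask row -> zero coefficient row
    gamma <- runif(1, 0.1, 1)
    C <- updateCRidge(Zs, L, A, B, Xs, R, gamma)
    expect_equal(C, oracleMaskedRidge(Zs, L, A, B, Xs, R, gamma),
                 tolerance = 1e-8)
    expect_identical(sum(C[1, ] != 0), 0L)
    expect_true(all(C[R == 0] == 0))
  }
  ## all-ones mask reduces to the textbook ridge closed form
  inst <- randStdInstance(3, 4, 10, seed = 109)
  Ra <- matrix(1, 3, 4)
  zeroA <- matrix(0, 1, 4); zeroB <- matrix(0, 3, 1)
  L0 <- matrix(0, 3, 10)
  C <- updateCRidge(inst$Zs, L0, zeroA, zeroB, inst$Xs, Ra, 0.3)
  Ctext <- inst$Zs %*% t(inst$Xs) %*%
    solve(tcrossprod(inst$Xs) + 0.3 * diag(4))
  expect_equal(C, Ctext, tolerance = 1e-10)
})

test_that("each penalty driven large zeroes its own block", {
  inst <- randStdInstance(8, 8, 16, seed = 110)
  opts <- fitOptions(maxSweeps = 5, innerMaxIter = 30)
  big <- 1e6
  expect_identical(sum(fitGeQTL(inst$Xs, inst$Zs, M = 2, alpha = big,
                                options = opts)@A != 0), 0L)
  expect_identical(sum(fitGeQTL(inst$Xs, inst$Zs, M = 2, beta = big,
                                options = opts)@B != 0), 0L)
  expect_identical(sum(fitGeQTL(inst$Xs, inst$Zs, M = 2, gamma = big,
                                options = opts)@C != 0), 0L)
  expect_identical(sum(fitGeQTL(inst$Xs, inst$Zs, M = 2, rho = big,
                                options = opts)@L != 0), 0L)
})

test_that("an all-zero mask freezes C at zero", {
  inst <- randStdInstance(5, 6, 14, seed = 111)
  fit <- fitGeQTL(inst$Xs, inst$Zs, M = 2, variant = "geqtl_plus",
                  mask = matrix(0, 5, 6),
                  options = fitOptions(maxSweeps = 5, innerMaxIter = 30))
  expect_identical(sum(indivAssoc(fit) != 0), 0L)
})

test_that("gene order permutation permutes the fit rows and preserves the
           objective", {
  sim <- simulateEQTL(K = 12, N = 10, H = 20, nGroups = 1L,
                      groupSizes = list(c(4L, 4L)), seed = 112)
  Xs <- standardizeRows(as.matrix(sim@X))
  Zs <- standardizeRows(as.matrix(sim@Z))
  opts <- fitOptions(maxSweeps = 8, innerMaxIter = 40)
  fit <- fitGeQTL(Xs, Zs, M = 2, options = opts)
  perm <- c(4, 1, 9, 2, 10, 3, 7, 5, 8, 6)
  fitP <- fitGeQTL(Xs, Zs[perm, ], M = 2, options = opts)
  expect_equal(unname(fitP@C), unname(fit@C[perm, ]), tolerance = 1e-8)
  expect_equal(unname(fitP@B), unname(fit@B[perm, ]), tolerance = 1e-8)
  expect_equal(unname(fitP@L), unname(fit@L[perm, ]), tolerance = 1e-8)
  expect_equal(tail(objectiveTrace(fitP), 1), tail(objectiveTrace(fit), 1),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("sample-id misalignment is rejected before fitting", {
  X <- GenotypeMatrix(matrix(c(0, 1, 2, 1, 0, 2), 2, 3,
                             dimnames = list(NULL, c("a", "b", "c"))))
  Z <- ExpressionMatrix(matrix(rnorm(6), 2, 3,
                               dimnames = list(NULL, c("a", "c", "b"))))
  expect_error(fitLasso(X, Z, eta = 0.1), "do not match")
})
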