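test_that("genotype synthesis is deterministic, coded 0/1/2, with the
           expected allele-frequency behavior", {
  X1 <- makeGenotypes(20, 30, seed = 11)
  X2 <- makeGenotypes(20, 30, seed = 11)
  expect_identical(as.matrix(X1), as.matrix(X2))
  expect_true(all(as.matrix(X1) %in% 0:2))

  ## maf pinned at 0.5: per-SNP mean genotype ~ Binomial(2H, .5)/H, so the
  ## overall mean should sit within 3 standard errors of 1
  Xh <- makeGenotypes(50, 2000, mafRange = c(0.5, 0.5), seed = 12)
  se <- sqrt(2 * 0.5 * 0.5 / (2000 * 50))
  expect_lt(abs(mean(as.matrix(Xh)) - 1), 3 * se)

  X3 <- makeGenotypes(4, 1, seed = 13)
  expect_identical(dim(X3), c(4L, 1L))
  expect_true(all(as.matrix(X3) %in% 0:2))

  expect_error(makeGenotypes(5, 5, mafRange = c(0, 0.6)), "mafRange")
})

test_that("ground-truth layout has the advertised block plus diagonal
           support", {
  tr <- makeTruth(100, 100)
  expect_length(tr@blocks, 4L)
  sizes <- vapply(tr@blocks, function(b) length(b$snps), integer(1))
  expect_identical(sizes, c(10L, 15L, 20L, 25L))
  ## support = four blocks (which straddle the diagonal) + the remaining
  ## diagonal cells
  blockCells <- sum(sizes * sizes)
  expect_identical(sum(tr@beta != 0), blockCells + (100L - sum(sizes)))

  expect_identical(sum(makeTruth(10, 10, nGroups = 0L,
                                 cisDiagonal = FALSE)@beta), 0)
  tr23 <- makeTruth(8, 9, nGroups = 1L, groupSizes = list(c(3L, 2L)),
                    cisDiagonal = FALSE)
  expect_identical(sum(tr23@beta != 0), 6L)
  expect_true(all(tr23@beta[tr23@beta != 0] == 1))

  expect_error(makeTruth(5, 5, nGroups = 1L, groupSizes = list(c(9L, 2L))),
               "do not fit")
})

test_that("expression decomposes exactly into signal, confounder and
           noise", {
  sim <- simulateEQTL(K = 25, N = 30, H = 40, seed = 21)
  recomposed <- sim@truth@beta %*% as.matrix(sim@X) + sim@truth@Xi +
    sim@truth@E
  expect_identical(unname(as.matrix(sim@Z)), unname(recomposed))

  ## noiseless limit
  sim0 <- simulateEQTL(K = 20, N = 20, H = 30, phi = 0, tau = 0, seed = 22)
  expect_equal(unname(as.matrix(sim0@Z)),
               unname(sim0@truth@beta %*% as.matrix(sim0@X)))

  ## pure-noise moments: with beta = 0 and tau = 0, entries are N(0, phi)
  simN <- simulateEQTL(K = 5, N = 200, H = 100, nGroups = 0L, phi = 0.25,
                       tau = 0, cisDiagonal = FALSE, seed = 23)
  expect_equal(var(as.vector(as.matrix(simN@Z))), 0.25, tolerance = 0.05)

  expect_identical(as.matrix(simulateEQTL(K = 10, N = 10, H = 10,
                                          seed = 24)@Z),
                   as.matrix(simulateEQTL(K = 10, N = 10, H = 10,
                                          seed = 24)@Z))
})

test_that("confounder rows follow the tau * F F^T covariance", {
  set.seed(31)
  H <- 12; J <- 3; tau <- 0.4
  tr <- makeTruth(6, 4000, nGroups = 0L, cisDiagonal = FALSE)
  X <- makeGenotypes(6, H, seed = 31)
  ze <- makeExpression(X, tr, phi = 0, tau = tau, J = J, seed = 32)
  Xi <- ze$truth@Xi
  empCov <- crossprod(Xi) / nrow(Xi)
  target <- tau * tcrossprod(ze$truth@F)
  relErr <- sqrt(sum((empCov - target)^2)) / sqrt(sum(target^2))
  expect_lt(relErr, 0.1)
})

test_that("snr follows its defining ratio and the calibration helper hits
           a requested target", {
  sim <- simulateEQTL(K = 15, N = 15, H = 25, seed = 41)
  s0 <- snr(sim)
  byHand <- sqrt(var(as.vector(sim@truth@beta %*% as.matrix(sim@X))) /
                 var(as.vector(sim@truth@Xi + sim@truth@E)))
  expect_equal(s0, byHand)

  ## doubling the noise components halves the SNR
  tr2 <- new("SimTruth", beta = sim@truth@beta, blocks = sim@truth@blocks,
             F = sim@truth@F, Xi = 2 * sim@truth@Xi, E = 2 * sim@truth@E)
  expect_equal(snr(tr2, sim@X), s0 / 2)

  trNull <- new("SimTruth", beta = sim@truth@beta * 0,
                blocks = sim@truth@blocks, F = sim@truth@F,
                Xi = sim@truth@Xi, E = sim@truth@E)
  expect_equal(snr(trNull, sim@X), 0)

  phi <- calibratePhi(0.13, seed = 99)
  realized <- vapply(1:5, function(s)
    snr(simulateEQTL(phi = phi, seed = s)), numeric(1))
  expect_equal(mean(realized), 0.13, tolerance = 0.15)
})

test_that("truth support is recoverable for ROC labeling", {
  sim <- simulateEQTL(K = 12, N = 12, H = 15, nGroups = 1L,
                      groupSizes = list(c(4L, 4L)), seed = 51)
  sup <- truthSupport(sim)
  expect_identical(sup, sim@truth@beta != 0)
  expect_identical(sum(sup), 16L + 12L - 4L)
})
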