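test_that("perfect weights reach the full partial area and a hand-worked
           grid matches enumeration", {
  truth <- matrix(c(1, 0, 0, 0, 1, 0, 0, 0, 1), 3, 3)
  r <- rocCurve(truth, truth, fprCap = 0.1)
  expect_equal(r@partialAuc, 0.1)

  ## 3x3 grid with hand-ordered distinct weights: the top-3 cells are the
  ## three positives, so tpr hits 1 while fpr is still 0
  w <- matrix(c(9, 1, 2, 3, 8, 4, 5, 6, 7), 3, 3)
  r2 <- rocCurve(w, truth, fprCap = 0.5)
  expect_equal(r2@tpr[r2@fpr == 0], c(0, 1/3, 2/3, 1))
  orc <- oracleRoc(w, truth, 0.5)
  expect_equal(r2@fpr, orc$fpr)
  expect_equal(r2@tpr, orc$tpr)
  expect_equal(r2@partialAuc, orc$pauc)
})

test_that("the sweep equals brute-force threshold enumeration on random
           instances", {
  set.seed(301)
  for (rep in 1:5) {
    w <- matrix(sample(50, 400, replace = TRUE), 20, 20)   # many ties
    truth <- matrix(rbinom(400, 1, 0.15), 20, 20)
    if (sum(truth) == 0) truth[1] <- 1
    r <- rocCurve(w, truth, fprCap = 0.1)
    orc <- oracleRoc(w, truth, 0.1)
    expect_equal(r@fpr, orc$fpr)
    expect_equal(r@tpr, orc$tpr)
    expect_equal(r@partialAuc, orc$pauc)
  }
})

test_that("partial AUC is invariant under rank-preserving transforms and
           handles the degenerate constant matrix", {
  set.seed(302)
  w <- matrix(runif(100), 10, 10)
  truth <- matrix(rbinom(100, 1, 0.2), 10, 10); truth[1] <- 1
  a <- rocCurve(w, truth)@partialAuc
  expect_equal(rocCurve(w^3, truth)@partialAuc, a)
  expect_equal(rocCurve(1000 * w, truth)@partialAuc, a)

  const <- matrix(1, 10, 10)
  rc <- rocCurve(const, truth, fprCap = 0.1)
  expect_length(rc@fpr, 1L)
  expect_equal(rc@partialAuc, 0.1 * rc@tpr)
})

test_that("random weights sit near the chance line", {
  set.seed(303)
  paucs <- replicate(40, {
    w <- matrix(rnorm(900), 30, 30)
    truth <- matrix(rbinom(900, 1, 0.2), 30, 30)
    rocCurve(w, truth, fprCap = 0.1)@partialAuc
  })
  expect_equal(mean(paucs), 0.1^2 / 2, tolerance = 0.15)
})

test_that("top-association overlap counts shared pairs", {
  l1 <- data.frame(gene_id = c("g1", "g2", "g3", "g4", "g5"),
                   snp_id  = c("s1", "s2", "s3", "s4", "s5"))
  expect_equal(topAssocOverlap(l1, l1, 3), 1)
  l2 <- data.frame(gene_id = c("g2", "g1", "g9", "g3", "g5"),
                   snp_id  = c("s2", "s1", "s9", "s3", "s5"))
  ## top-4 lists share (g1,s1), (g2,s2), (g3,s3): 3 of 4
  expect_equal(topAssocOverlap(l1, l2, 4), 0.75)
  expect_equal(topAssocOverlap(l2, l1, 4), 0.75)   # symmetric
  l3 <- data.frame(gene_id = paste0("h", 1:5), snp_id = paste0("t", 1:5))
  expect_equal(topAssocOverlap(l1, l3, 5), 0)
  expect_error(topAssocOverlap(l1, l2, 0), "between 1")
})

test_that("hotspot overlap ranks SNPs by regulatory degree with stable
           ties", {
  ## 6 SNPs; degrees in set1: s1=3, s2=2, s3=2, s4=1, s5=0, s6=0
  a1 <- data.frame(
    gene_id = c("g1", "g2", "g3", "g1", "g2", "g1", "g2", "g1"),
    snp_id  = c("s1", "s1", "s1", "s2", "s2", "s3", "s3", "s4"))
  ## degrees in set2: s1=3, s2=2, s6=2, s4=1
  a2 <- data.frame(
    gene_id = c("g1", "g2", "g3", "g1", "g2", "g1", "g2", "g3"),
    snp_id  = c("s1", "s1", "s1", "s2", "s2", "s6", "s6", "s4"))
  snps <- paste0("s", 1:6)
  expect_equal(hotspotOverlap(a1, a1, 3, snpIds = snps), 1)
  ## top-3 of set1: s1, s2, s3 (tie s2/s3 broken by id order);
  ## top-3 of set2: s1, s2, s6 -> share {s1, s2}
  expect_equal(hotspotOverlap(a1, a2, 3, snpIds = snps), 2 / 3)
  expect_equal(hotspotOverlap(a2, a1, 3, snpIds = snps), 2 / 3)
  ## one dominant SNP in both
  expect_equal(hotspotOverlap(a1, a2, 1, snpIds = snps), 1)
})

test_that("association tables rank by absolute total weight with the
           documented columns", {
  sim <- simulateEQTL(K = 8, N = 6, H = 15, nGroups = 1L,
                      groupSizes = list(c(3L, 3L)), seed = 304)
  fit <- fitGeQTL(sim@X, sim@Z, M = 1,
                  options = fitOptions(maxSweeps = 5, innerMaxIter = 30))
  tab <- associationTable(fit)
  expect_named(tab, c("gene_id", "snp_id", "weight_total",
                      "weight_individual", "weight_groupwise"))
  expect_identical(nrow(tab), 48L)
  expect_true(all(diff(abs(tab$weight_total)) <= 1e-12))
  expect_equal(tab$weight_total,
               tab$weight_individual + tab$weight_groupwise)
})
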