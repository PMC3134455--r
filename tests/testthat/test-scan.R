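test_that("precomputeOffsets forms neighbour sums excluding self-edges", {
  # zero couplings give zero offsets
  y <- c(1L, 0L, 1L)
  expect_equal(unname(precomputeOffsets(diag(1, 3), y)), rep(0, 3),
               ignore_attr = TRUE)
  # n = 3, all-ones off-diagonal, y = (1,1,0): s = (+1,+1,-1)
  A <- matrix(1, 3, 3)
  r <- precomputeOffsets(A, c(1L, 1L, 0L))
  expect_equal(unname(r), c(0, 0, 2), ignore_attr = TRUE)
  # permuting individuals permutes the offsets identically
  set.seed(17)
  n <- 12
  U <- matrix(runif(n * n), n, n); Asym <- (U + t(U)) / 2; diag(Asym) <- 1
  yr <- rbinom(n, 1, 0.5)
  r0 <- precomputeOffsets(Asym, yr)
  pi <- sample(n)
  r1 <- precomputeOffsets(Asym[pi, pi], yr[pi])
  expect_equal(unname(r1), unname(r0)[pi], tolerance = 1e-12,
               ignore_attr = TRUE)
  # centring subtracts the off-diagonal mean from every coupling
  rc <- precomputeOffsets(Asym, yr, center = TRUE)
  mbar <- mean(Asym[upper.tri(Asym)])
  s <- 2 * yr - 1
  expect_equal(unname(rc), unname(r0) - mbar * (sum(s) - s),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("testSnp flags degenerate SNPs and matches the logistic sandwich oracle", {
  set.seed(23)
  n <- 200
  XBase <- cbind(intercept = rep(1, n))
  y <- rbinom(n, 1, 0.5)
  # constant column is untestable, flagged not dropped
  res <- testSnp(rep(0, n), XBase, y, rep(0, n), snpId = "flat")
  expect_false(res$converged)
  expect_true(is.na(res$p))
  # A = 0: weight, robust SE and p match the IRLS + sandwich oracle
  for (rep in 1:5) {
    snp <- as.numeric(scale(rbinom(n, 2, 0.3)))
    yy <- rbinom(n, 1, plogis(0.3 * snp))
    res <- testSnp(snp, XBase, yy, rep(0, n), coupling = "none")
    oracle <- glmSandwichOracle(yy, cbind(XBase, snp = snp))
    expect_equal(res$beta, unname(oracle$coef["snp"]) / 2, tolerance = 1e-6)
    expect_equal(res$se, sqrt(oracle$vcov["snp", "snp"]) / 2, tolerance = 1e-6)
    chiOracle <- (oracle$coef["snp"])^2 / oracle$vcov["snp", "snp"]
    expect_equal(res$chi2, unname(chiOracle), tolerance = 1e-6)
    expect_equal(res$p, unname(pchisq(chiOracle, 1, lower.tail = FALSE)),
                 tolerance = 1e-6)
  }
})

test_that("null p-values are approximately uniform without couplings", {
  # type-I error of the A = 0 path over many independent null SNPs
  set.seed(29)
  n <- 150
  nSnps <- 600
  XBase <- cbind(intercept = rep(1, n))
  y <- rbinom(n, 1, 0.5)
  ps <- vapply(seq_len(nSnps), function(j) {
    snp <- as.numeric(scale(rbinom(n, 2, runif(1, 0.1, 0.5))))
    testSnp(snp, XBase, y, rep(0, n), coupling = "none")$p
  }, numeric(1))
  frac <- mean(ps < 0.05)
  ciHalf <- 2.576 * sqrt(0.05 * 0.95 / nSnps)  # binomial 99% CI
  expect_lt(abs(frac - 0.05), ciHalf + 0.01)
})

test_that("runScan is deterministic, order-invariant and id-checked", {
  set.seed(37)
  pop <- populationConfig(nIndividuals = 50, nSnps = 20, seed = 11)
  ds <- buildBenchmark(pop, betaGrid = 0, reps = 1)[[1]]
  geno <- genotypes(ds)
  y <- phenotypes(ds)
  scan <- runScan(geno, y, similarity = ds@similarity)
  tab <- resultsTable(scan)
  expect_identical(tab$snp_id, snpIds(geno))

  # m = 1 equals a direct testSnp call with shared offsets
  g1 <- GenotypeMatrix(genotypes(geno)[, 1, drop = FALSE])
  scan1 <- runScan(g1, y, similarity = ds@similarity)
  expect_equal(resultsTable(scan1)$p, tab$p[1], tolerance = 1e-10)

  # duplicated SNP column gives identical statistics
  G2 <- cbind(genotypes(geno), dup = genotypes(geno)[, 3])
  scan2 <- runScan(GenotypeMatrix(G2), y, similarity = ds@similarity)
  t2 <- resultsTable(scan2)
  expect_equal(t2$chi2[nrow(t2)], t2$chi2[3], tolerance = 1e-10)

  # SNP-order invariance
  perm <- sample(20)
  scanP <- runScan(GenotypeMatrix(genotypes(geno)[, perm]), y,
                   similarity = ds@similarity)
  expect_equal(resultsTable(scanP)$chi2, tab$chi2[perm], tolerance = 1e-8)

  # individual permutation applied to all inputs leaves results unchanged
  ids <- sampleIds(geno)
  piv <- sample(length(ids))
  scanI <- runScan(GenotypeMatrix(genotypes(geno)[piv, ]), y[piv],
                   similarity = SimilarityMatrix(
                     similarityValues(ds)[piv, piv]))
  expect_equal(resultsTable(scanI)$chi2, tab$chi2, tolerance = 1e-8)

  # Wald statistic identity on the stored table
  ok <- tab$converged
  expect_equal(tab$chi2[ok], (tab$beta[ok] / tab$se[ok])^2, tolerance = 1e-12)

  # id mismatch errors and names the offender
  ybad <- y
  names(ybad)[1] <- "stranger"
  expect_error(runScan(geno, ybad), "stranger")
})
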