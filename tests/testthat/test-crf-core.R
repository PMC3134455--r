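test_that("unnormalizedLogJoint matches single-edge cases and a brute-force sum", {
  # empty exponent
  X <- cbind(rep(1, 3))
  A0 <- diag(1, 3)
  for (y in list(c(0L, 0L, 0L), c(1L, 0L, 1L)))
    expect_equal(unnormalizedLogJoint(y, X, 0, A0), 0)
  # single edge: +a when spins agree, -a otherwise
  a <- 0.37
  A <- matrix(c(1, a, a, 1), 2, 2)
  X2 <- cbind(rep(1, 2))
  expect_equal(unnormalizedLogJoint(c(1L, 1L), X2, 0, A), a)
  expect_equal(unnormalizedLogJoint(c(0L, 0L), X2, 0, A), a)
  expect_equal(unnormalizedLogJoint(c(1L, 0L), X2, 0, A), -a)
  # random instance vs term-by-term oracle
  set.seed(21)
  for (rep in 1:10) {
    inst <- randomInstance(6, p = 3)
    expect_equal(unnormalizedLogJoint(inst$y, inst$X, inst$w, inst$A),
                 bruteLogJoint(inst$y, inst$X, inst$w, inst$A),
                 tolerance = 1e-12)
  }
  expect_error(unnormalizedLogJoint(c(0L, 1L), X, c(0, 0), A0), "mismatch")
})

test_that("logPartitionBruteForce agrees with factorization and enumeration", {
  # uniform over 8 states
  X <- cbind(rep(1, 3))
  expect_equal(logPartitionBruteForce(X, 0, matrix(0, 3, 3) + diag(3)), log(8))
  # A = 0 factorizes over individuals
  set.seed(4)
  n <- 6
  Xr <- cbind(1, rnorm(n))
  w <- c(0.3, -0.7)
  b <- drop(Xr %*% w)
  expect_equal(logPartitionBruteForce(Xr, w, diag(1, n)),
               sum(log(exp(b) + exp(-b))), tolerance = 1e-10)
  # full 2^8 enumeration oracle
  inst <- randomInstance(8, p = 2)
  cfg <- allConfigs(8)
  vals <- apply(cfg, 1, function(y) bruteLogJoint(y, inst$X, inst$w, inst$A))
  expect_equal(logPartitionBruteForce(inst$X, inst$w, inst$A),
               log(sum(exp(vals - max(vals)))) + max(vals),
               tolerance = 1e-10)
  expect_error(logPartitionBruteForce(matrix(1, 21, 1), 0, diag(21)), "20")
})

test_that("conditionalProb equals exact conditionals from the joint", {
  # symmetry
  X <- cbind(rep(1, 4))
  expect_equal(conditionalProb(2, c(0L, 1L, 0L, 1L), X, 0, diag(1, 4)), 0.5)
  # exact-joint oracle at n <= 10
  set.seed(31)
  for (rep in 1:10) {
    n <- sample(3:10, 1)
    inst <- randomInstance(n, p = 2)
    i <- sample(n, 1)
    expect_equal(conditionalProb(i, inst$y, inst$X, inst$w, inst$A),
                 bruteConditional(i, inst$y, inst$X, inst$w, inst$A),
                 tolerance = 1e-10)
  }
  # monotone in the coupling offset
  probs <- vapply(c(0.1, 0.4, 0.9), function(a) {
    A <- matrix(c(1, a, a, 1), 2, 2)
    conditionalProb(1, c(0L, 1L), cbind(rep(1, 2)), 0, A)
  }, numeric(1))
  expect_true(all(diff(probs) > 0))
})

test_that("negLogPseudolikelihood is the sum of conditional terms and convex", {
  # all conditionals 0.5
  n <- 7
  X <- cbind(rep(1, n))
  y <- rbinom(n, 1, 0.5)
  expect_equal(negLogPseudolikelihood(0, y, X, rep(0, n)), n * log(2))
  # per-term oracle and positivity
  set.seed(41)
  for (rep in 1:5) {
    inst <- randomInstance(6, p = 3)
    offs <- precomputeOffsets(inst$A, inst$y)
    npl <- negLogPseudolikelihood(inst$w, inst$y, inst$X, offs)
    terms <- vapply(1:6, function(i) {
      pi1 <- conditionalProb(i, inst$y, inst$X, inst$w, inst$A)
      -log(if (inst$y[i] == 1) pi1 else 1 - pi1)
    }, numeric(1))
    expect_gt(npl, 0)
    expect_equal(npl, sum(terms), tolerance = 1e-10)
    # midpoint convexity
    w1 <- rnorm(3); w2 <- rnorm(3)
    fmid <- negLogPseudolikelihood((w1 + w2) / 2, inst$y, inst$X, offs)
    fend <- (negLogPseudolikelihood(w1, inst$y, inst$X, offs) +
             negLogPseudolikelihood(w2, inst$y, inst$X, offs)) / 2
    expect_lte(fmid, fend + 1e-12)
  }
})

test_that("plGradient and plHessian match finite differences", {
  set.seed(51)
  for (rep in 1:5) {
    inst <- randomInstance(12, p = 3)
    offs <- precomputeOffsets(inst$A, inst$y)
    f <- function(w) negLogPseudolikelihood(w, inst$y, inst$X, offs)
    g <- plGradient(inst$w, inst$y, inst$X, offs)
    expect_equal(g, fdGradient(f, inst$w),
                 tolerance = 1e-6, ignore_attr = TRUE)
    H <- plHessian(inst$w, inst$y, inst$X, offs)
    Hfd <- t(vapply(seq_along(inst$w), function(k) {
      e <- rep(0, 3); e[k] <- 1e-5
      (plGradient(inst$w + e, inst$y, inst$X, offs) -
       plGradient(inst$w - e, inst$y, inst$X, offs)) / 2e-5
    }, numeric(3)))
    expect_equal(H, Hfd, tolerance = 1e-5, ignore_attr = TRUE)
    expect_true(all(eigen(H, symmetric = TRUE, only.values = TRUE)$values >= -1e-10))
  }
  # saturated probabilities flatten the Hessian
  inst <- randomInstance(10, p = 2)
  offs <- rep(0, 10)
  Hbig <- plHessian(c(1e4, 0), inst$y, inst$X, offs)
  expect_lt(max(abs(Hbig)), 1e-6)
})

test_that("plGradient reduces to the logistic score when A is zero", {
  set.seed(61)
  n <- 30
  X <- cbind(1, rnorm(n))
  y <- rbinom(n, 1, 0.5)
  w <- c(0.2, -0.4)
  g <- plGradient(w, y, X, rep(0, n))
  # independent logistic score on the doubled design: predictor 2 X w
  mu <- 1 / (1 + exp(-drop(2 * X %*% w)))
  scoreOracle <- drop(crossprod(2 * X, mu - y))
  expect_equal(g, scoreOracle, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("scoreOuterProduct is a PSD sum of per-individual outer products", {
  set.seed(71)
  inst <- randomInstance(15, p = 3)
  offs <- precomputeOffsets(inst$A, inst$y)
  B <- scoreOuterProduct(inst$w, inst$y, inst$X, offs)
  expect_equal(B, t(B))
  expect_true(all(eigen(B, symmetric = TRUE, only.values = TRUE)$values >= -1e-10))
  # trace identity via per-individual recomputation
  kappa <- 2
  pii <- plogis(kappa * (drop(inst$X %*% inst$w) + offs))
  gi <- inst$X * (kappa * (pii - inst$y))
  expect_equal(sum(diag(B)), sum(rowSums(gi^2)), tolerance = 1e-10)
  # single-observation case: B = g g^T exactly
  B1 <- scoreOuterProduct(inst$w, inst$y[1], inst$X[1, , drop = FALSE], offs[1])
  expect_equal(unname(B1), outer(gi[1, ], gi[1, ]), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("robustVariance sandwiches H and B correctly", {
  set.seed(81)
  M <- matrix(rnorm(9), 3, 3)
  H <- crossprod(M) + diag(0.5, 3)
  B <- crossprod(matrix(rnorm(9), 3, 3)) + diag(0.2, 3)
  expect_equal(unname(robustVariance(H, H)), unname(solve(H)),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(unname(robustVariance(diag(1, 3), B)), unname((B + t(B)) / 2),
               tolerance = 1e-12, ignore_attr = TRUE)
  # 2x2 cofactor-inversion oracle
  H2 <- matrix(c(2, 0.3, 0.3, 1.5), 2, 2)
  B2 <- matrix(c(1, 0.2, 0.2, 0.8), 2, 2)
  det2 <- H2[1, 1] * H2[2, 2] - H2[1, 2] * H2[2, 1]
  Hi2 <- matrix(c(H2[2, 2], -H2[2, 1], -H2[1, 2], H2[1, 1]), 2, 2) / det2
  expect_equal(unname(robustVariance(H2, B2)), Hi2 %*% B2 %*% Hi2,
               tolerance = 1e-12, ignore_attr = TRUE)
  # singular bread is pseudo-inverted with a warning
  expect_warning(S <- robustVariance(matrix(1, 2, 2), diag(2)), "singular")
  expect_true(attr(S, "singular"))
})

test_that("fitCRF recovers the logistic MLE when A is zero", {
  set.seed(91)
  for (rep in 1:3) {
    n <- 120
    X <- cbind(intercept = 1, x = rnorm(n))
    y <- rbinom(n, 1, plogis(0.4 * X[, 2]))
    fit <- fitCRF(y, X, offsets = NULL, coupling = "none", tol = 1e-10)
    oracle <- glmSandwichOracle(y, X)
    # spin-encoding fit works on the doubled design: weights halve
    expect_equal(unname(weights(fit)), unname(oracle$coef) / 2,
                 tolerance = 1e-6)
    expect_equal(unname(sandwichVariance(fit)), unname(oracle$vcov) / 4,
                 tolerance = 1e-6, ignore_attr = TRUE)
    expect_true(converged(fit))
  }
})

test_that("fitCRF reaches the same optimum from any start and via gd", {
  set.seed(101)
  inst <- randomInstance(60, p = 3, scaleA = 0.1)
  offs <- precomputeOffsets(inst$A, inst$y, center = TRUE)
  fits <- lapply(1:3, function(k)
    fitCRF(inst$y, inst$X, offs, coupling = "fitted",
           start = rnorm(4, sd = 2), tol = 1e-10))
  for (k in 2:3)
    expect_equal(weights(fits[[k]]), weights(fits[[1]]), tolerance = 1e-6)
  gd <- fitCRF(inst$y, inst$X, offs, coupling = "fitted", optimizer = "gd",
               eta = 0.01, tol = 1e-6, maxIter = 20000)
  expect_equal(weights(gd), weights(fits[[1]]), tolerance = 1e-4)
})

test_that("fitCRF drops collinear columns with a warning", {
  set.seed(111)
  n <- 40
  X <- cbind(intercept = 1, a = rnorm(n))
  X <- cbind(X, dup = X[, "a"])
  y <- rbinom(n, 1, 0.5)
  expect_warning(fit <- fitCRF(y, X, coupling = "none"), "collinear")
  expect_identical(fit@droppedColumns, "dup")
  expect_true(is.na(weights(fit)["dup"]))
  expect_false(is.na(weights(fit)["a"]))
})

test_that("gibbsSampleCRF reproduces exact joint frequencies on small graphs", {
  # independence case: marginals 0.5
  n <- 6
  X <- cbind(rep(1, n))
  draws <- gibbsSampleCRF(X, 0, diag(1, n), nSweeps = 50, nSamples = 2000,
                          thin = 1, seed = 5)
  m <- colMeans(draws)
  se <- sqrt(0.25 / 2000)  # conservative: ignores autocorrelation (none here)
  expect_true(all(abs(m - 0.5) < 4 * se))
  # same seed -> identical draw
  d1 <- gibbsSampleCRF(X, 0, diag(1, n), nSweeps = 10, seed = 99)
  d2 <- gibbsSampleCRF(X, 0, diag(1, n), nSweeps = 10, seed = 99)
  expect_identical(d1, d2)

  # exact-enumeration oracle on a coupled n = 5 model
  set.seed(121)
  inst <- randomInstance(5, p = 2, scaleA = 0.3)
  cfg <- allConfigs(5)
  lp <- apply(cfg, 1, function(y) bruteLogJoint(y, inst$X, inst$w, inst$A))
  pExact <- exp(lp - max(lp)); pExact <- pExact / sum(pExact)
  draws <- gibbsSampleCRF(inst$X, inst$w, inst$A, nSweeps = 200,
                          nSamples = 6000, thin = 3, seed = 6)
  key <- draws %*% 2^(0:4)
  pHat <- tabulate(key + 1, nbins = 32) / nrow(draws)
  expect_lt(max(abs(pHat - pExact)), 0.02)

  # ferromagnetic couplings raise pair concordance
  Astrong <- matrix(0.4, 8, 8); diag(Astrong) <- 1
  X8 <- cbind(rep(1, 8))
  conc <- function(A) {
    dr <- gibbsSampleCRF(X8, 0, A, nSweeps = 50, nSamples = 800, thin = 2,
                         seed = 8)
    mean(apply(dr, 1, function(y) mean(outer(y, y, "==")[upper.tri(diag(8))])))
  }
  expect_gt(conc(Astrong), conc(diag(1, 8)) + 0.05)
})

test_that("pseudo-likelihood estimates sharpen as n grows on CRF data", {
  # well-specified recovery: data Gibbs-sampled at known weights
  set.seed(131)
  err <- vapply(c(60, 480), function(n) {
    X <- cbind(intercept = 1, snp = rnorm(n))
    # constant, subcritical total coupling (keeps the chain paramagnetic)
    A <- matrix(0.4 / n, n, n); diag(A) <- 1
    mean(vapply(1:20, function(r) {
      y <- gibbsSampleCRF(X, c(0, 0.5), A, nSweeps = 60, seed = 1000 + r)
      offs <- precomputeOffsets(A, y)
      fit <- fitCRF(y, X, offs, coupling = "fixed", tol = 1e-9)
      abs(weights(fit)["snp"] - 0.5)
    }, numeric(1)))
  }, numeric(1))
  expect_lt(err[2], err[1])
})

test_that("offset precompute is quadratic once; per-iteration cost is linear", {
  set.seed(141)
  counts <- vapply(c(100, 200), function(n) {
    A <- matrix(0.1, n, n); diag(A) <- 1
    y <- rbinom(n, 1, 0.5)
    offs <- precomputeOffsets(A, y, center = TRUE)
    expect_equal(attr(offs, "ops"), n * (n - 1))
    X <- cbind(intercept = 1, snp = rnorm(n))
    fit <- fitCRF(y, X, offs, coupling = "fitted", tol = 1e-9)
    fit@opCount / max(fit@iterations, 1)
  }, numeric(1))
  # doubling n should roughly double per-iteration work, never square it
  expect_lt(counts[2] / counts[1], 2.6)
  expect_gt(counts[2] / counts[1], 1.4)
})
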