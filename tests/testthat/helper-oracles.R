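# Independent oracles used across the suite.  These are deliberately
# written in the most literal (slow) form so they share no code path with
# the implementation they check.

# per-locus allele-sharing IBS, brute force over individual pairs
bruteIBS <- function(G) {
  n <- nrow(G)
  A <- diag(1, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    num <- 0
    den <- 0
    for (l in seq_len(ncol(G))) {
      gi <- G[i, l]; gj <- G[j, l]
      if (is.na(gi) || is.na(gj)) next
      # count shared alleles between the two unordered allele pairs
      ai <- c(rep(1, gi), rep(0, 2 - gi))
      aj <- c(rep(1, gj), rep(0, 2 - gj))
      num <- num + min(sum(ai), sum(aj)) + min(sum(1 - ai), sum(1 - aj))
      den <- den + 2
    }
    A[i, j] <- num / den
  }
  A
}

# term-by-term log joint exponent (spin encoding), independent summation
bruteLogJoint <- function(y, X, w, A) {
  s <- 2 * y - 1
  tot <- 0
  for (i in seq_along(y)) tot <- tot + s[i] * sum(w * X[i, ])
  for (i in seq_along(y)) for (j in seq_along(y)) {
    if (i < j) tot <- tot + A[i, j] * s[i] * s[j]
  }
  tot
}

# all 2^n configurations as rows of a 0/1 matrix
allConfigs <- function(n) {
  cfg <- matrix(0L, 2^n, n)
  for (k in seq_len(2^n)) {
    v <- k - 1L
    for (b in seq_len(n)) {
      cfg[k, b] <- v %% 2L
      v <- v %/% 2L
    }
  }
  cfg
}

# exact conditional P(y_i = 1 | y_-i) from full enumeration of the joint
bruteConditional <- function(i, y, X, w, A) {
  y1 <- y; y1[i] <- 1L
  y0 <- y; y0[i] <- 0L
  e1 <- bruteLogJoint(y1, X, w, A)
  e0 <- bruteLogJoint(y0, X, w, A)
  1 / (1 + exp(e0 - e1))
}

# random CRF instance (spin encoding), similarity-like A in [0, 1]
randomInstance <- function(n, p = 2, scaleA = 0.5) {
  X <- cbind(1, matrix(rnorm(n * (p - 1)), n, p - 1))
  colnames(X) <- c("intercept", if (p > 1) paste0("c", seq_len(p - 1)))
  U <- matrix(runif(n * n), n, n) * scaleA
  A <- (U + t(U)) / 2
  diag(A) <- 1
  list(y = rbinom(n, 1, 0.5), X = X, w = rnorm(p, sd = 0.5), A = A)
}

# central finite differences of a scalar function
fdGradient <- function(f, w, h = 1e-6) {
  vapply(seq_along(w), function(k) {
    e <- rep(0, length(w)); e[k] <- h
    (f(w + e) - f(w - e)) / (2 * h)
  }, numeric(1))
}

# logistic-regression IRLS + HC0 sandwich oracle (design D, offset o):
# returns coef, sandwich vcov and Wald p for the named column
glmSandwichOracle <- function(y, D, offset = rep(0, length(y))) {
  fit <- glm.fit(D, y, family = binomial(), offset = offset)
  beta <- fit$coefficients
  eta <- drop(D %*% beta) + offset
  mu <- plogis(eta)
  Wi <- mu * (1 - mu)
  H <- crossprod(D * Wi, D)
  Gm <- D * (y - mu)
  B <- crossprod(Gm)
  Hi <- solve(H)
  V <- Hi %*% B %*% Hi
  list(coef = beta, vcov = V)
}

# exhaustive pairwise AUC oracle (ties count 1/2)
bruteAUC <- function(pNull, pAlt) {
  tot <- 0
  for (a in pAlt) for (b in pNull)
    tot <- tot + if (a < b) 1 else if (a == b) 0.5 else 0
  tot / (length(pAlt) * length(pNull))
}

# tiny genotype fixture with ids
fixtureGenotypes <- function() {
  GenotypeMatrix(rbind(s1 = c(0L, 1L, 2L, 0L),
                       s2 = c(1L, 1L, 2L, NA),
                       s3 = c(2L, 0L, 1L, 1L),
                       s4 = c(0L, 2L, 0L, 2L)),
                 snpIds = paste0("rs", 1:4))
}
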