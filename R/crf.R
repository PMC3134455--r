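# Pairwise conditional random field over binary phenotypes.
#
# The joint model over phenotype labels y (0/1, spin view s = 2y - 1),
# conditioned on per-individual design rows x_i and fixed pairwise
# similarities A, has unnormalized log-probability
#
#     sum_i s_i (w . x_i)  +  sum_{i<j} A_ij s_i s_j ,
#
# normalized by a partition function summing over all 2^n label
# configurations.  The conditional of one label given all others is
# logistic -- sigma(2 (w . x_i + r_i)) with coupling offset
# r_i = sum_{j != i} A_ij s_j -- so the pseudo-likelihood (product of
# conditionals) never touches the partition function and its optimisation
# is a convex logistic-regression-with-offset problem.  An alternative
# {0,1} label encoding is available: there the pair potential is
# A_ij y_i y_j and the conditional is sigma(w . x_i + sum A_ij y_j).

# operation counter: counts data-touching floating point work so the
# linear-per-iteration cost contract can be asserted without wall clocks
.opCounter <- new.env(parent = emptyenv())
.opCounter$n <- 0
.opReset <- function() .opCounter$n <- 0
.opAdd <- function(k) .opCounter$n <- .opCounter$n + k
.opGet <- function() .opCounter$n

.encodingScale <- function(encoding) {
    encoding <- match.arg(encoding, c("spin", "binary"))
    if (encoding == "spin") 2 else 1
}

.stateVector <- function(y, encoding) {
    if (encoding == "spin") 2 * y - 1 else y
}

#' Unnormalized log joint probability of the phenotype CRF
#'
#' Evaluates the exponent of the joint model:
#' `sum_i s_i (w . x_i) + sum_(i<j) A[i,j] s_i s_j` in the spin encoding
#' (`s = 2y - 1`), or the analogous expression with `y` in place of `s`
#' under the binary encoding.  The diagonal of `A` is ignored (self-edges
#' excluded).
#'
#' @param y 0/1 phenotype vector of length n.
#' @param X numeric design matrix (n x p), one row per individual.
#' @param w numeric weight vector of length p.
#' @param A n x n symmetric similarity matrix (a [SimilarityMatrix-class]
#'   or plain matrix).
#' @param encoding `"spin"` (default) or `"binary"` label encoding.
#' @return a single numeric value.
#' @export
unnormalizedLogJoint <- function(y, X, w, A, encoding = c("spin", "binary")) {
    encoding <- match.arg(encoding)
    if (is(A, "SimilarityMatrix")) A <- A@values
    X <- as.matrix(X)
    n <- length(y)
    if (nrow(X) != n || ncol(X) != length(w) || nrow(A) != n || ncol(A) != n)
        stop("dimension mismatch among y, X, w, A")
    s <- .stateVector(y, encoding)
    A0 <- A
    diag(A0) <- 0
    sum(s * drop(X %*% w)) + 0.5 * drop(s %*% A0 %*% s)
}

#' Log partition function by exhaustive enumeration
#'
#' Computes `log Z = log sum over all 2^n configurations of
#' exp(unnormalizedLogJoint)` with overflow-safe (log-sum-exp)
#' accumulation.  Intended as an exact small-n oracle; refuses n > 20.
#'
#' @inheritParams unnormalizedLogJoint
#' @return log of the partition function.
#' @export
logPartitionBruteForce <- function(X, w, A, encoding = c("spin", "binary")) {
    encoding <- match.arg(encoding)
    if (is(A, "SimilarityMatrix")) A <- A@values
    X <- as.matrix(X)
    n <- nrow(X)
    if (n > 20) stop("brute-force partition function limited to n <= 20")
    A0 <- A
    diag(A0) <- 0
    b <- drop(X %*% w)
    configs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))[, n:1, drop = FALSE]
    S <- if (encoding == "spin") 2 * configs - 1 else configs
    vals <- drop(S %*% b) + 0.5 * rowSums((S %*% A0) * S)
    mx <- max(vals)
    mx + log(sum(exp(vals - mx)))
}

#' Conditional probability of one phenotype given all others
#'
#' `P(y_i = 1 | y_-i, X, A)` under the pairwise CRF.  In the spin encoding
#' this is `sigma(2 (w . x_i + r_i))` with `r_i = sum_(j != i) A[i,j] s_j`;
#' the partition function cancels out of the conditional, which is what
#' makes pseudo-likelihood estimation tractable.
#'
#' @param i individual index (1-based).
#' @inheritParams unnormalizedLogJoint
#' @return probability in (0, 1).
#' @export
conditionalProb <- function(i, y, X, w, A, encoding = c("spin", "binary")) {
    encoding <- match.arg(encoding)
    if (is(A, "SimilarityMatrix")) A <- A@values
    X <- as.matrix(X)
    s <- .stateVector(y, encoding)
    r <- sum(A[i, -i] * s[-i])
    kappa <- .encodingScale(encoding)
    plogis(kappa * (sum(w * X[i, ]) + r))
}

#' Coupling offsets for pseudo-likelihood fitting
#'
#' Precomputes, once per (similarity, phenotype) pair, the additive
#' per-individual term `r_i = sum_(j != i) M[i,j] s_j` that carries the
#' contribution of all other individuals' phenotypes into individual i's
#' conditional.  `M` is the similarity matrix with self-edges removed,
#' optionally centred by subtracting the off-diagonal mean similarity
#' (recommended for association scans: the raw IBS baseline is large and
#' its aggregate term would otherwise scale with the sample's label
#' imbalance rather than with genetic structure; see the package
#' vignette).  The computation costs O(n^2) and is independent of the SNP
#' being tested, so a genome scan performs it exactly once.
#'
#' @param A a [SimilarityMatrix-class] or plain symmetric matrix.
#' @param y 0/1 phenotype vector.
#' @param center subtract the off-diagonal mean similarity before forming
#'   the sums (default `FALSE` at this level; the scan layer defaults to
#'   `TRUE`).
#' @param encoding label encoding; the spin view uses `s = 2y - 1`, the
#'   binary view uses `y` itself.
#' @return numeric offset vector of length n; attributes `ops` (operation
#'   count `n (n - 1)`) and `center` record the computation.
#' @export
precomputeOffsets <- function(A, y, center = FALSE,
                              encoding = c("spin", "binary")) {
    encoding <- match.arg(encoding)
    if (is(A, "SimilarityMatrix")) A <- A@values
    n <- length(y)
    if (nrow(A) != n) stop("dimension mismatch between A and y")
    M <- A
    if (center) {
        mbar <- mean(A[upper.tri(A)])
        M <- A - mbar
    }
    diag(M) <- 0
    s <- .stateVector(y, encoding)
    r <- drop(M %*% s)
    names(r) <- names(y)
    attr(r, "ops") <- n * (n - 1)
    attr(r, "center") <- center
    r
}

# linear predictor of the conditionals: kappa * (X w + offsets)
.plEta <- function(w, X, offsets, kappa) {
    .opAdd(length(offsets) * length(w))
    kappa * (drop(X %*% w) + offsets)
}

#' Negative log-pseudo-likelihood
#'
#' `-sum_i log P(y_i | y_-i)` under the pairwise CRF, evaluated from the
#' precomputed coupling offsets.  Convex in `w` (it is a logistic
#' log-likelihood in a scaled design), and always non-negative.
#'
#' @param w weight vector (length p).
#' @param y 0/1 phenotype vector (length n).
#' @param X design matrix (n x p).
#' @param offsets coupling offsets from [precomputeOffsets()] (or zeros).
#' @param encoding label encoding matching the offsets.
#' @return a single non-negative numeric value.
#' @export
negLogPseudolikelihood <- function(w, y, X, offsets,
                                   encoding = c("spin", "binary")) {
    encoding <- match.arg(encoding)
    X <- as.matrix(X)
    kappa <- .encodingScale(encoding)
    eta <- .plEta(w, X, offsets, kappa)
    q <- ifelse(y == 1, eta, -eta)
    -sum(plogis(q, log.p = TRUE))
}

#' Gradient of the negative log-pseudo-likelihood
#'
#' Exact gradient `sum_i kappa (pi_i - y_i) x_i` where
#' `pi_i = sigma(kappa (w . x_i + r_i))` and `kappa` is 2 under the spin
#' encoding (1 under the binary encoding).
#'
#' @inheritParams negLogPseudolikelihood
#' @return numeric vector of length p.
#' @export
plGradient <- function(w, y, X, offsets, encoding = c("spin", "binary")) {
    encoding <- match.arg(encoding)
    X <- as.matrix(X)
    kappa <- .encodingScale(encoding)
    pii <- plogis(.plEta(w, X, offsets, kappa))
    .opAdd(nrow(X) * ncol(X))
    drop(crossprod(X, kappa * (pii - y)))
}

#' Hessian of the negative log-pseudo-likelihood
#'
#' `H = sum_i kappa^2 pi_i (1 - pi_i) x_i x_i^T`; symmetric positive
#' semidefinite everywhere (the objective is convex).
#'
#' @inheritParams negLogPseudolikelihood
#' @return p x p numeric matrix.
#' @export
plHessian <- function(w, y, X, offsets, encoding = c("spin", "binary")) {
    encoding <- match.arg(encoding)
    X <- as.matrix(X)
    kappa <- .encodingScale(encoding)
    pii <- plogis(.plEta(w, X, offsets, kappa))
    .opAdd(nrow(X) * ncol(X)^2)
    crossprod(X * (kappa^2 * pii * (1 - pii)), X)
}

#' Outer product of per-individual score contributions
#'
#' `B = sum_i g_i g_i^T` where `g_i = kappa (pi_i - y_i) x_i` is individual
#' i's contribution to the pseudo-likelihood gradient.  Together with the
#' Hessian this forms the robust (sandwich) variance estimator.
#'
#' @inheritParams negLogPseudolikelihood
#' @return p x p symmetric positive semidefinite matrix.
#' @export
scoreOuterProduct <- function(w, y, X, offsets,
                              encoding = c("spin", "binary")) {
    encoding <- match.arg(encoding)
    X <- as.matrix(X)
    kappa <- .encodingScale(encoding)
    pii <- plogis(.plEta(w, X, offsets, kappa))
    G <- X * (kappa * (pii - y))
    .opAdd(nrow(X) * ncol(X)^2)
    crossprod(G)
}

#' Robust (sandwich) variance estimator
#'
#' `Sigma = H^-1 B H^-1`, the Huber-style variance estimate that remains
#' valid when the working conditional independence of the pseudo-likelihood
#' is misspecified.  A numerically singular Hessian is pseudo-inverted with
#' a warning and the result carries `attr(, "singular") = TRUE` so callers
#' can flag the SNP as untestable.
#'
#' @param H Hessian matrix from [plHessian()].
#' @param B score outer product from [scoreOuterProduct()].
#' @return symmetric p x p variance matrix.
#' @export
robustVariance <- function(H, B) {
    p <- nrow(H)
    singular <- FALSE
    Hi <- tryCatch({
        R <- chol(H)
        chol2inv(R)
    }, error = function(e) NULL)
    if (is.null(Hi) || !all(is.finite(Hi)) || rcond(H) < 1e-12) {
        warning("numerically singular Hessian; using pseudo-inverse")
        Hi <- MASS::ginv(H)
        singular <- TRUE
    }
    S <- Hi %*% B %*% Hi
    S <- (S + t(S)) / 2
    attr(S, "singular") <- singular
    S
}

#' Fit the pairwise CRF by pseudo-likelihood
#'
#' Minimises the negative log-pseudo-likelihood over the weight vector.
#' The objective is convex with a unique optimum, so the default Newton
#' optimizer (with step halving) and plain gradient descent (`"gd"`,
#' mirroring the update `w <- w - eta * grad`) reach the same solution.
#'
#' The coupling offsets can enter in three ways:
#' \describe{
#'   \item{`"fitted"` (default)}{the offset vector is appended to the
#'     design as one extra column `.coupling` whose scalar weight is
#'     estimated jointly with the rest -- the problem stays convex, and the
#'     strength of the phenotype-coupling correction is calibrated to the
#'     data (analogous to estimating the genetic variance component in a
#'     mixed model).  If the offsets are identically zero the column is
#'     dropped and the fit reduces to ordinary logistic regression.}
#'   \item{`"fixed"`}{the offsets enter as a fixed additive term with unit
#'     weight, the strict pseudo-likelihood of the CRF whose couplings are
#'     exactly `A`.}
#'   \item{`"none"`}{offsets ignored (plain logistic regression).}
#' }
#'
#' Exactly collinear design columns are detected by rank-revealing QR and
#' dropped with a warning; their weights are reported as `NA`.
#'
#' @param y 0/1 phenotype vector.
#' @param X design matrix including an intercept column.
#' @param offsets coupling offsets from [precomputeOffsets()]; `NULL` for
#'   none.
#' @param coupling `"fitted"`, `"fixed"` or `"none"` (see Details).
#' @param optimizer `"newton"` (default) or `"gd"`.
#' @param eta learning rate for `"gd"` (default 0.01).
#' @param tol convergence tolerance on the gradient max-norm (default 1e-8).
#' @param maxIter iteration cap (default 500).
#' @param encoding label encoding.
#' @param start optional start for the weights (default zeros).
#' @return a [CRFFit-class] object.
#' @export
fitCRF <- function(y, X, offsets = NULL,
                   coupling = c("fitted", "fixed", "none"),
                   optimizer = c("newton", "gd"),
                   eta = 0.01, tol = 1e-8, maxIter = 500L,
                   encoding = c("spin", "binary"), start = NULL) {
    coupling <- match.arg(coupling)
    optimizer <- match.arg(optimizer)
    encoding <- match.arg(encoding)
    X <- as.matrix(X)
    storage.mode(X) <- "double"
    if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
    n <- length(y)
    if (nrow(X) != n) stop("dimension mismatch between y and X")
    if (is.null(offsets)) offsets <- rep(0, n)
    if (coupling != "none" && all(abs(offsets) < 1e-12)) coupling <- "none"
    if (coupling == "fitted") {
        X <- cbind(X, .coupling = as.numeric(offsets))
        offs <- rep(0, n)
    } else if (coupling == "fixed") {
        offs <- as.numeric(offsets)
    } else {
        offs <- rep(0, n)
    }

    # collinearity: drop columns beyond the numerical rank
    fullNames <- colnames(X)
    qrX <- qr(X)
    dropped <- character()
    if (qrX$rank < ncol(X)) {
        keep <- sort(qrX$pivot[seq_len(qrX$rank)])
        dropped <- fullNames[-keep]
        warning("dropping collinear design column(s): ",
                paste(dropped, collapse = ", "))
        X <- X[, keep, drop = FALSE]
    }
    p <- ncol(X)

    w <- if (is.null(start)) rep(0, p) else {
        stopifnot(length(start) == p)
        as.numeric(start)
    }
    .opReset()
    obj <- negLogPseudolikelihood(w, y, X, offs, encoding)
    iter <- 0L
    convergedFlag <- FALSE
    g <- plGradient(w, y, X, offs, encoding)
    while (iter < maxIter) {
        if (max(abs(g)) <= tol) {
            convergedFlag <- TRUE
            break
        }
        iter <- iter + 1L
        if (optimizer == "newton") {
            H <- plHessian(w, y, X, offs, encoding)
            step <- tryCatch(solve(H + diag(1e-10, p), g),
                             error = function(e) eta * g)
            # step halving keeps the descent monotone even when
            # probabilities saturate and H is nearly flat
            lam <- 1
            repeat {
                wNew <- w - lam * step
                objNew <- negLogPseudolikelihood(wNew, y, X, offs, encoding)
                if (objNew <= obj + 1e-12 || lam < 1e-8) break
                lam <- lam / 2
            }
            w <- wNew
            obj <- objNew
        } else {
            w <- w - eta * g
            obj <- negLogPseudolikelihood(w, y, X, offs, encoding)
        }
        g <- plGradient(w, y, X, offs, encoding)
    }
    if (!convergedFlag && max(abs(g)) <= tol) convergedFlag <- TRUE
    if (!convergedFlag)
        warning(sprintf("fitCRF did not converge in %d iterations (|grad| = %.2e)",
                        maxIter, max(abs(g))))

    H <- plHessian(w, y, X, offs, encoding)
    B <- scoreOuterProduct(w, y, X, offs, encoding)
    Sig <- suppressWarnings(robustVariance(H, B))
    singular <- isTRUE(attr(Sig, "singular"))
    attr(Sig, "singular") <- NULL
    ops <- .opGet()

    wFull <- structure(rep(NA_real_, length(fullNames)), names = fullNames)
    wFull[colnames(X)] <- w
    gFull <- structure(rep(NA_real_, length(fullNames)), names = fullNames)
    gFull[colnames(X)] <- g
    dimnames(H) <- dimnames(B) <- dimnames(Sig) <- list(colnames(X), colnames(X))
    new("CRFFit", weights = wFull, negLogPL = obj, gradient = gFull,
        hessian = H, scoreOuter = B, sandwich = Sig,
        iterations = iter, converged = convergedFlag,
        gradNorm = max(abs(g)), droppedColumns = dropped,
        singularHessian = singular, opCount = ops)
}

#' Gibbs sampling from the phenotype CRF
#'
#' Systematic-scan Gibbs sampler drawing label configurations from the
#' joint CRF, using the closed-form conditionals.  Exact joint sampling is
#' intractable for more than ~20 individuals (the partition function sums
#' 2^n terms); the Gibbs chain provides approximate samples for
#' parameter-recovery experiments.  Reproducible given `seed`.
#'
#' @param X design matrix (n x p).
#' @param w weight vector.
#' @param A similarity matrix (couplings), diagonal ignored.
#' @param nSweeps burn-in sweeps before the first retained sample
#'   (default 100).
#' @param nSamples number of retained configurations (default 1).
#' @param thin sweeps between retained samples (default 1).
#' @param seed optional integer seed.
#' @param encoding label encoding.
#' @param init optional initial 0/1 configuration (default random).
#' @return an integer 0/1 vector when `nSamples = 1`, otherwise an
#'   `nSamples` x n integer matrix.
#' @export
gibbsSampleCRF <- function(X, w, A, nSweeps = 100L, nSamples = 1L, thin = 1L,
                           seed = NULL, encoding = c("spin", "binary"),
                           init = NULL) {
    encoding <- match.arg(encoding)
    if (is(A, "SimilarityMatrix")) A <- A@values
    X <- as.matrix(X)
    n <- nrow(X)
    kappa <- .encodingScale(encoding)
    if (!is.null(seed)) set.seed(seed)
    b <- drop(X %*% w)
    A0 <- A
    diag(A0) <- 0
    y <- if (is.null(init)) rbinom(n, 1L, 0.5) else as.integer(init)
    s <- .stateVector(y, encoding)
    r <- drop(A0 %*% s)
    totalSweeps <- nSweeps + (nSamples - 1L) * thin + if (nSamples > 0) 1L else 0L
    out <- matrix(NA_integer_, nSamples, n)
    colnames(out) <- rownames(X)
    sampleAt <- nSweeps + 1L + (seq_len(nSamples) - 1L) * thin
    k <- 1L
    for (sw in seq_len(totalSweeps)) {
        u <- runif(n)
        for (i in seq_len(n)) {
            pii <- plogis(kappa * (b[i] + r[i]))
            yi <- as.integer(u[i] < pii)
            if (yi != y[i]) {
                dS <- if (encoding == "spin") 2 * (yi - y[i]) else yi - y[i]
                r <- r + A0[, i] * dS
                y[i] <- yi
            }
        }
        if (k <= nSamples && sw == sampleAt[k]) {
            out[k, ] <- y
            k <- k + 1L
        }
    }
    if (nSamples == 1L) structure(drop(out), names = rownames(X)) else out
}
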