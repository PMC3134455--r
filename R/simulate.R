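# Structured-population synthetic data: Balding-Nichols subpopulations,
# family blocks sharing parental haplotypes, and binary phenotypes sampled
# from a generalized linear mixed model whose random effect covaries as
# sigma^2 * K with K the IBS similarity matrix.  The generator supplies,
# without any external download, data carrying the confounding signature
# the CRF scan is designed to remove.

#' Configuration for the structured genotype simulator
#'
#' Defaults mimic the structure of family-based association panels drawn
#' from several ancestry groups: four subpopulations differentiated at
#' F_ST = 0.1 and family blocks of six individuals (two parents plus four
#' offspring, close to the ~5.9 individuals-per-family ratio of typical
#' three-generation family studies).
#'
#' @param nIndividuals number of individuals (>= 2).
#' @param nSnps number of SNPs (>= 1).
#' @param nSubpops number of subpopulations (default 4).
#' @param fst Wright's fixation index in (0, 1) controlling subpopulation
#'   differentiation (default 0.1).
#' @param familyBlockSize individuals per family block (default 6; 1 means
#'   unrelated individuals).  Remainders form a smaller final block.
#' @param seed mandatory integer seed.
#' @return a classed list of settings.
#' @export
populationConfig <- function(nIndividuals, nSnps, nSubpops = 4L, fst = 0.1,
                             familyBlockSize = 6L, seed) {
    stopifnot(nIndividuals >= 2, nSnps >= 1, nSubpops >= 1,
              fst > 0, fst < 1, familyBlockSize >= 1)
    if (missing(seed)) stop("a seed is required")
    structure(list(nIndividuals = as.integer(nIndividuals),
                   nSnps = as.integer(nSnps),
                   nSubpops = as.integer(nSubpops), fst = fst,
                   familyBlockSize = as.integer(familyBlockSize),
                   seed = as.integer(seed)),
              class = "populationConfig")
}

#' Configuration for the GLMM phenotype sampler
#'
#' @param snpWeight true regression weight of the causal SNP (0 for null).
#' @param variance random-effect variance sigma^2 >= 0 (default 1).
#' @param targetPrevalence phenotype frequency to match, strictly in
#'   (0, 1) (default 0.5).
#' @param covariateWeights weights for covariate columns (default none).
#' @param seed mandatory integer seed.
#' @return a classed list of settings.
#' @export
glmmConfig <- function(snpWeight = 0, variance = 1, targetPrevalence = 0.5,
                       covariateWeights = numeric(), seed) {
    stopifnot(variance >= 0, targetPrevalence > 0, targetPrevalence < 1)
    if (missing(seed)) stop("a seed is required")
    structure(list(snpWeight = snpWeight, variance = variance,
                   targetPrevalence = targetPrevalence,
                   covariateWeights = covariateWeights,
                   seed = as.integer(seed)),
              class = "glmmConfig")
}

#' Simulate structured genotypes
#'
#' Balding-Nichols model: ancestral allele frequencies are drawn from
#' Uniform(0.1, 0.9); each subpopulation's frequency is drawn from
#' Beta(p (1 - F) / F, (1 - p) (1 - F) / F), so that the across-
#' subpopulation variance of the frequency is F p (1 - p).  Within each
#' subpopulation, individuals are organised into family blocks: the first
#' two members are parents with genotypes Binomial(2, p_sub); each further
#' member is a child who samples one allele from each parent.  Genotypes
#' are reported as allele counts for the allele that is minor in the
#' ancestral population.  Bit-reproducible given the config seed.
#'
#' @param cfg a [populationConfig()].
#' @return a [GenotypeMatrix-class]; `attr(, "subpop")` records each
#'   individual's subpopulation and `attr(, "family")` its family block.
#' @export
simulateGenotypes <- function(cfg) {
    stopifnot(inherits(cfg, "populationConfig"))
    set.seed(cfg$seed)
    n <- cfg$nIndividuals
    m <- cfg$nSnps
    fst <- cfg$fst
    pAnc <- runif(m, 0.1, 0.9)
    subpop <- sort(rep_len(seq_len(cfg$nSubpops), n))
    G <- matrix(0L, n, m)
    family <- integer(n)
    famId <- 0L
    for (k in seq_len(cfg$nSubpops)) {
        idx <- which(subpop == k)
        pk <- rbeta(m, pAnc * (1 - fst) / fst, (1 - pAnc) * (1 - fst) / fst)
        pk <- pmin(pmax(pk, 1e-6), 1 - 1e-6)
        pos <- 1L
        while (pos <= length(idx)) {
            famId <- famId + 1L
            blk <- idx[pos:min(pos + cfg$familyBlockSize - 1L, length(idx))]
            family[blk] <- famId
            gp1 <- rbinom(m, 2L, pk)
            gp2 <- rbinom(m, 2L, pk)
            G[blk[1L], ] <- gp1
            if (length(blk) > 1L) G[blk[2L], ] <- gp2
            if (length(blk) > 2L)
                for (child in blk[-(1:2)])
                    G[child, ] <- rbinom(m, 1L, gp1 / 2) + rbinom(m, 1L, gp2 / 2)
            pos <- pos + cfg$familyBlockSize
        }
    }
    out <- GenotypeMatrix(G,
                          individualIds = sprintf("ind%0*d", nchar(n), seq_len(n)),
                          snpIds = sprintf("snp%0*d", nchar(m), seq_len(m)))
    attr(out, "subpop") <- subpop
    attr(out, "family") <- family
    out
}

#' Solve for the prevalence-matching intercept
#'
#' Finds the constant `c` such that `mean(plogis(eta + c))` equals the
#' target phenotype frequency.  The mean is strictly increasing in `c`, so
#' bisection always brackets the unique root; the returned value satisfies
#' the target to within 1e-8.
#'
#' @param linearPredictors numeric vector of linear predictors eta.
#' @param target desired phenotype frequency, strictly in (0, 1).
#' @return the offset `c`.
#' @examples
#' solvePrevalenceOffset(rep(0, 10), 0.75)  # log(3)
#' @export
solvePrevalenceOffset <- function(linearPredictors, target) {
    stopifnot(target > 0, target < 1)
    f <- function(c0) mean(plogis(linearPredictors + c0)) - target
    lo <- -1
    hi <- 1
    while (f(lo) > 0) lo <- lo * 2
    while (f(hi) < 0) hi <- hi * 2
    for (i in 1:200) {
        mid <- (lo + hi) / 2
        if (f(mid) < 0) lo <- mid else hi <- mid
        if (hi - lo < 1e-12) break
    }
    (lo + hi) / 2
}

#' Simulate binary phenotypes from a GLMM
#'
#' Draws a random effect `u ~ Normal(0, sigma^2 K)` (adding a 1e-6 jitter
#' to the diagonal if `K` is not numerically positive definite), forms the
#' linear predictor `eta_i = beta * snp_i + covariate terms + u_i`, shifts
#' it by the prevalence-matching offset from [solvePrevalenceOffset()],
#' and samples `y_i ~ Bernoulli(plogis(eta_i + c))`.  Interpreting the
#' similarity matrix as the covariance `K` of the random effect transfers
#' the genetic structure into the phenotypes, creating the confounding
#' that the association scan must correct.
#'
#' @param snp optional causal SNP column (standardized or raw; used as
#'   given), or `NULL`.
#' @param X optional covariate matrix matching
#'   `length(cfg$covariateWeights)` columns.
#' @param K similarity matrix ([SimilarityMatrix-class] or plain matrix)
#'   used as the random-effect correlation.
#' @param cfg a [glmmConfig()].
#' @return named integer 0/1 vector of phenotypes.
#' @export
simulatePhenotypesGLMM <- function(snp = NULL, X = NULL, K, cfg) {
    stopifnot(inherits(cfg, "glmmConfig"))
    if (is(K, "SimilarityMatrix")) K <- K@values
    n <- nrow(K)
    set.seed(cfg$seed)
    eta <- rep(0, n)
    if (cfg$variance > 0) {
        L <- tryCatch(chol(K), error = function(e)
            tryCatch(chol(K + diag(1e-6, n)), error = function(e2)
                stop("K is not positive semidefinite, even after jitter")))
        eta <- eta + sqrt(cfg$variance) * drop(crossprod(L, rnorm(n)))
    }
    if (!is.null(snp)) eta <- eta + cfg$snpWeight * snp
    if (length(cfg$covariateWeights)) {
        if (is.null(X) || ncol(X) != length(cfg$covariateWeights))
            stop("X must supply one column per covariate weight")
        eta <- eta + drop(as.matrix(X) %*% cfg$covariateWeights)
    }
    c0 <- solvePrevalenceOffset(eta, cfg$targetPrevalence)
    y <- rbinom(n, 1L, plogis(eta + c0))
    names(y) <- rownames(K)
    y
}

#' Build a benchmark collection of synthetic datasets
#'
#' For each SNP regression weight in `betaGrid` and each replicate,
#' produces a [SyntheticDataset-class] with known truth labels: one
#' genotype panel and its IBS matrix are generated once from `cfgPop` and
#' shared by every dataset (as when a fixed real genotype panel is reused
#' across phenotype simulations), while phenotypes are drawn independently
#' per dataset from the GLMM, with the causal SNP (for non-zero weights)
#' cycling through the common SNPs of the panel (sample MAF >= 0.05; an
#' effect cannot be attached to a monomorphic or near-monomorphic locus)
#' so successive replicates probe different loci.  The grid must contain
#' 0: null datasets are the false-positive reference for ROC analysis.
#'
#' @param cfgPop a [populationConfig()].
#' @param betaGrid numeric vector of SNP weights; must contain 0.
#'   Default `c(0, 0.1, 0.2, 0.5)`.
#' @param reps replicates per grid value; either a single count or one
#'   count per entry of `betaGrid`.
#' @param variance,targetPrevalence GLMM settings shared by all datasets.
#' @return a list of [SyntheticDataset-class] objects, one per
#'   (beta, replicate) pair, in grid-major order.
#' @export
buildBenchmark <- function(cfgPop, betaGrid = c(0, 0.1, 0.2, 0.5), reps = 1L,
                           variance = 1, targetPrevalence = 0.5) {
    stopifnot(inherits(cfgPop, "populationConfig"))
    if (!any(betaGrid == 0))
        stop("betaGrid must contain 0 (null SNPs are the FP reference)")
    if (length(reps) == 1L) reps <- rep(reps, length(betaGrid))
    stopifnot(length(reps) == length(betaGrid))
    geno <- simulateGenotypes(cfgPop)
    sim <- computeIBS(geno)
    G <- genotypes(geno)
    Z <- .prepareSnpColumns(G)
    m <- ncol(G)
    maf <- colMeans(G) / 2
    maf <- pmin(maf, 1 - maf)
    eligible <- which(maf >= 0.05)
    if (!length(eligible) && any(betaGrid != 0))
        stop("no SNP with MAF >= 0.05 to carry a non-zero effect")
    emptyCov <- CovariateMatrix(
        matrix(numeric(0), nrow(G), 0, dimnames = list(rownames(G), NULL)))
    out <- list()
    counter <- 0L
    for (bi in seq_along(betaGrid)) {
        b <- betaGrid[bi]
        for (r in seq_len(reps[bi])) {
            counter <- counter + 1L
            causal <- if (b != 0)
                eligible[((r - 1L) %% length(eligible)) + 1L] else NA_integer_
            cfgG <- glmmConfig(snpWeight = b, variance = variance,
                               targetPrevalence = targetPrevalence,
                               seed = cfgPop$seed + 7919L * counter)
            y <- simulatePhenotypesGLMM(
                snp = if (!is.na(causal)) Z[, causal] else NULL,
                K = sim, cfg = cfgG)
            truth <- rep(0, m)
            names(truth) <- colnames(G)
            if (!is.na(causal)) truth[causal] <- b
            out[[counter]] <- new("SyntheticDataset", genotypes = geno,
                                  covariates = emptyCov,
                                  phenotypes = structure(as.integer(y),
                                                         names = names(y)),
                                  similarity = sim, truth = truth,
                                  config = list(beta = b, rep = r,
                                                causal = causal,
                                                pop = unclass(cfgPop),
                                                glmm = unclass(cfgG)))
        }
    }
    out
}
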