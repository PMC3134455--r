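#' Identity-by-state similarity matrix
#'
#' Computes the pairwise identity-by-state (IBS) similarity between all
#' individuals: the fraction of SNP marker alleles shared between the two
#' individuals across the panel.  Treating each genotype as an unordered
#' pair of alleles, a locus with minor-allele counts g_i and g_j contributes
#' a shared fraction (2 - |g_i - g_j|) / 2, and the IBS value is the mean
#' over loci that are non-missing in both individuals.  Encoded in the full
#' SNP panel, these similarities capture population structure, family
#' structure and cryptic relatedness, and serve as the fixed edge weights
#' of the phenotype CRF.
#'
#' @param geno a [GenotypeMatrix-class].
#' @return a [SimilarityMatrix-class]; entries in [0, 1], unit diagonal.
#'   A pair of individuals with no jointly observed locus is an error.
#' @examples
#' g <- GenotypeMatrix(rbind(a = c(0, 1, 2), b = c(1, 1, 2)))
#' similarityValues(computeIBS(g))["a", "b"]  # 5/6
#' @export
computeIBS <- function(geno) {
    stopifnot(is(geno, "GenotypeMatrix"))
    G <- genotypes(geno)
    n <- nrow(G)
    obs <- !is.na(G)
    Gz <- G
    Gz[!obs] <- 0L
    storage.mode(Gz) <- "double"
    obs <- obs * 1
    # |g_i - g_j| summed over jointly observed loci, via the expansion
    # sum |gi - gj| = sum over shared loci; use squared counts identity:
    # for entries in {0,1,2}, |a-b| = (a-b)^2 - [(a-b)^2 == 4] * 2 ... not
    # linear, so accumulate per genotype level instead.
    shared <- obs %*% t(obs)                 # jointly observed locus counts
    if (any(shared[upper.tri(shared)] == 0)) {
        bad <- which(shared == 0 & upper.tri(shared), arr.ind = TRUE)[1, ]
        stop(sprintf("individuals '%s' and '%s' share no non-missing locus",
                     rownames(G)[bad[1]], rownames(G)[bad[2]]))
    }
    # indicator matrices per genotype value (zeroed where missing)
    I0 <- (Gz == 0) * obs
    I1 <- (Gz == 1) * obs
    I2 <- (Gz == 2) * obs
    # count of loci with |gi - gj| = 1 and = 2 for each pair
    d1 <- I0 %*% t(I1) + I1 %*% t(I0) + I1 %*% t(I2) + I2 %*% t(I1)
    d2 <- I0 %*% t(I2) + I2 %*% t(I0)
    A <- 1 - (d1 + 2 * d2) / (2 * shared)
    diag(A) <- 1
    SimilarityMatrix(A, individualIds = rownames(G))
}

#' Standardize covariates to column z-scores
#'
#' Centers each column to zero mean and scales to unit standard deviation,
#' using the population (divide-by-n) standard deviation.  Constant columns
#' cannot be scaled; they are mapped to all-zeros, recorded in
#' `constantColumns`, and a warning is raised.  Applying the function to an
#' already-standardized matrix leaves it unchanged.
#'
#' @param cov a [CovariateMatrix-class], matrix or data.frame.
#' @return a standardized [CovariateMatrix-class].
#' @export
standardizeCovariates <- function(cov) {
    if (!is(cov, "CovariateMatrix")) cov <- CovariateMatrix(cov)
    v <- cov@values
    const <- character()
    if (ncol(v)) {
        for (j in seq_len(ncol(v))) {
            x <- v[, j]
            mu <- mean(x)
            s <- sqrt(mean((x - mu)^2))
            if (s < 1e-12) {
                v[, j] <- 0
                const <- c(const, colnames(v)[j])
            } else {
                v[, j] <- (x - mu) / s
            }
        }
        if (length(const))
            warning("constant covariate column(s) zeroed: ",
                    paste(const, collapse = ", "))
    }
    CovariateMatrix(v, standardized = TRUE,
                    constantColumns = union(const, cov@constantColumns))
}

# population-sd z-score of a single numeric vector (0 if constant)
.standardizeVector <- function(x) {
    mu <- mean(x)
    s <- sqrt(mean((x - mu)^2))
    if (s < 1e-12) rep(0, length(x)) else (x - mu) / s
}

#' One-hot age-bin covariates
#'
#' Bins ages into five ranges delimited by four cut points and encodes each
#' individual's bin as a binary 5-vector (one-hot indicator columns).  Bins
#' follow the half-open convention `[lo, hi)`: an age equal to a cut point
#' falls in the upper bin.  By default the cut points are the interior
#' quintiles of the input ages.
#'
#' @param ages numeric vector of ages; must be finite and not below
#'   `start`.
#' @param edges four strictly increasing cut points, or `NULL` for
#'   quintiles of `ages`.
#' @param start lower limit of the first bin (default `-Inf`); an age
#'   below it is an error.
#' @return a [CovariateMatrix-class] with five 0/1 columns; every row sums
#'   to 1.
#' @examples
#' covariateValues(binAges(c(25, 40, 70), edges = c(20, 35, 50, 65)))
#' @export
binAges <- function(ages, edges = NULL, start = -Inf) {
    if (any(!is.finite(ages))) stop("ages must be finite")
    if (is.null(edges))
        edges <- unname(quantile(ages, c(0.2, 0.4, 0.6, 0.8), type = 7))
    if (length(edges) != 4L || any(diff(edges) <= 0))
        stop("edges must be 4 strictly increasing cut points")
    if (start >= edges[1]) stop("start must lie below the first cut point")
    if (any(ages < start)) stop("age below the first bin start")
    breaks <- c(-Inf, edges, Inf)
    bin <- findInterval(ages, breaks)  # half-open [lo, hi) bins
    v <- matrix(0, length(ages), 5L,
                dimnames = list(names(ages), paste0("age_bin", 1:5)))
    v[cbind(seq_along(ages), bin)] <- 1
    CovariateMatrix(v)
}

#' Filter SNPs on minor-allele frequency and missingness
#'
#' Retains SNPs whose sample minor-allele frequency is at least `mafMin`
#' and whose missing fraction is at most `missingMax`.  The MAF is the
#' minor-allele count divided by twice the number of non-missing genotypes;
#' because genotypes are coded as minor-allele counts, frequencies above
#' 0.5 are folded.
#'
#' @param geno a [GenotypeMatrix-class].
#' @param mafMin minimum minor-allele frequency in [0, 0.5].
#' @param missingMax maximum missing fraction in [0, 1].
#' @return the filtered [GenotypeMatrix-class]; the retained SNP ids are
#'   also available as `attr(, "keptSnps")`.  Removing every SNP is an
#'   error.
#' @export
filterSNPs <- function(geno, mafMin = 0, missingMax = 1) {
    stopifnot(is(geno, "GenotypeMatrix"),
              mafMin >= 0, mafMin <= 0.5, missingMax >= 0, missingMax <= 1)
    G <- genotypes(geno)
    nObs <- colSums(!is.na(G))
    missFrac <- 1 - nObs / nrow(G)
    maf <- colSums(G, na.rm = TRUE) / pmax(2 * nObs, 1)
    maf <- pmin(maf, 1 - maf)
    keep <- maf >= mafMin & missFrac <= missingMax & nObs > 0
    if (!any(keep)) stop("all SNPs removed by filtering")
    out <- GenotypeMatrix(G[, keep, drop = FALSE])
    attr(out, "keptSnps") <- colnames(G)[keep]
    out
}
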