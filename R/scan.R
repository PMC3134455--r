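#' Wald test of a single SNP under the CRF
#'
#' Fits the CRF by pseudo-likelihood with design `[XBase | snp]`, computes
#' the sandwich variance, and returns the Wald chi-square statistic
#' `(w_snp / se)^2` compared against the chi-square distribution with one
#' degree of freedom (null SNP weight 0, two-sided).  A SNP whose
#' standardized column is constant, collinear with the covariates, whose
#' fit fails to converge, or whose Hessian is singular, is returned flagged
#' (`converged = FALSE`, `NA` statistics) rather than dropped.
#'
#' @param snp standardized numeric SNP column (length n).
#' @param XBase base design matrix with intercept and covariates.
#' @param y 0/1 phenotype vector.
#' @param offsets coupling offsets from [precomputeOffsets()].
#' @param snpId label used in the output row.
#' @param coupling,optimizer,eta,tol,maxIter,encoding passed to [fitCRF()].
#' @return one-row data.frame: snp_id, beta, se, chi2, p, converged.
#' @export
testSnp <- function(snp, XBase, y, offsets, snpId = "snp",
                    coupling = "fitted", optimizer = "newton", eta = 0.01,
                    tol = 1e-8, maxIter = 500L, encoding = "spin") {
    flagged <- data.frame(snp_id = snpId, beta = NA_real_, se = NA_real_,
                          chi2 = NA_real_, p = NA_real_, converged = FALSE,
                          stringsAsFactors = FALSE)
    if (sd(snp) < 1e-12) return(flagged)
    X <- cbind(as.matrix(XBase), snp = snp)
    fit <- tryCatch(
        suppressWarnings(fitCRF(y, X, offsets, coupling = coupling,
                                optimizer = optimizer, eta = eta, tol = tol,
                                maxIter = maxIter, encoding = encoding)),
        error = function(e) NULL)
    if (is.null(fit)) return(flagged)
    w <- fit@weights["snp"]
    if (!fit@converged || is.na(w) || fit@singularHessian) {
        flagged$beta <- unname(w)
        return(flagged)
    }
    v <- fit@sandwich["snp", "snp"]
    if (!is.finite(v) || v <= 0) return(flagged)
    se <- sqrt(v)
    chi2 <- (unname(w) / se)^2
    data.frame(snp_id = snpId, beta = unname(w), se = se, chi2 = chi2,
               p = pchisq(chi2, df = 1, lower.tail = FALSE),
               converged = TRUE, stringsAsFactors = FALSE)
}

# mean-impute missing genotypes and standardize each SNP column
.prepareSnpColumns <- function(G) {
    apply(G, 2, function(g) {
        if (anyNA(g)) g[is.na(g)] <- mean(g, na.rm = TRUE)
        .standardizeVector(g)
    })
}

#' Genome-wide association scan under the phenotype CRF
#'
#' Runs the per-SNP scan: aligns all inputs by individual id, filters SNPs,
#' computes (or accepts) the IBS similarity matrix, precomputes the
#' coupling offsets once (the only O(n^2) step), then fits the CRF and
#' performs the robust Wald test for every SNP column in turn.  Missing
#' genotypes are mean-imputed per SNP before standardization; every SNP
#' column and covariate is standardized to zero mean and unit (population)
#' standard deviation.  The scan is deterministic given its inputs, and its
#' output order follows the input SNP order.
#'
#' Setting `coupling = "none"` (or passing a zero similarity matrix) gives
#' the naive logistic-regression scan that ignores relatedness -- the
#' comparator used when demonstrating the calibration contrast under
#' population structure.
#'
#' @param geno a [GenotypeMatrix-class].
#' @param pheno named 0/1 vector (names are individual ids), or unnamed
#'   vector aligned with `geno`.
#' @param covariates optional [CovariateMatrix-class], matrix or
#'   data.frame of per-individual covariates.
#' @param similarity optional [SimilarityMatrix-class]; computed with
#'   [computeIBS()] from the filtered panel when `NULL` and
#'   `coupling != "none"`.
#' @param mafMin,missingMax SNP filters (see [filterSNPs()]).
#' @param coupling,optimizer,eta,tol,maxIter,encoding fitting controls, see
#'   [fitCRF()].
#' @param center centre the similarity matrix when forming offsets
#'   (default `TRUE`; see [precomputeOffsets()]).
#' @return a [ScanResult-class].
#' @examples
#' set.seed(1)
#' pop <- populationConfig(nIndividuals = 60, nSnps = 40, seed = 7)
#' ds <- buildBenchmark(pop, betaGrid = 0, reps = 1)[[1]]
#' scan <- runScan(genotypes(ds), phenotypes(ds))
#' head(resultsTable(scan))
#' @export
runScan <- function(geno, pheno, covariates = NULL, similarity = NULL,
                    mafMin = 0, missingMax = 1,
                    coupling = c("fitted", "fixed", "none"),
                    center = TRUE, optimizer = c("newton", "gd"),
                    eta = 0.01, tol = 1e-8, maxIter = 500L,
                    encoding = c("spin", "binary")) {
    coupling <- match.arg(coupling)
    optimizer <- match.arg(optimizer)
    encoding <- match.arg(encoding)
    stopifnot(is(geno, "GenotypeMatrix"))
    ids <- sampleIds(geno)

    if (!is.null(names(pheno))) {
        missing <- setdiff(ids, names(pheno))
        extra <- setdiff(names(pheno), ids)
        if (length(missing) || length(extra))
            stop("individual ids do not match between genotypes and phenotypes; ",
                 "unmatched: ",
                 paste(c(missing, extra), collapse = ", "))
        pheno <- pheno[ids]
    } else if (length(pheno) != length(ids)) {
        stop("unnamed phenotype vector must match the number of individuals")
    }
    y <- as.integer(pheno)
    if (!all(y %in% c(0L, 1L))) stop("phenotypes must be binary 0/1")

    XBase <- matrix(1, length(ids), 1, dimnames = list(ids, "intercept"))
    if (!is.null(covariates)) {
        if (!is(covariates, "CovariateMatrix"))
            covariates <- CovariateMatrix(as.matrix(covariates))
        cv <- covariateValues(covariates)
        if (!is.null(rownames(cv)) && all(ids %in% rownames(cv))) {
            cv <- cv[ids, , drop = FALSE]
        } else if (nrow(cv) != length(ids)) {
            stop("covariate rows missing for ids: ",
                 paste(setdiff(ids, rownames(cv)), collapse = ", "))
        }
        if (!isStandardized(covariates))
            cv <- covariateValues(standardizeCovariates(CovariateMatrix(cv)))
        XBase <- cbind(XBase, cv)
    }

    geno <- filterSNPs(geno, mafMin = mafMin, missingMax = missingMax)
    G <- genotypes(geno)

    if (coupling != "none") {
        if (is.null(similarity)) similarity <- computeIBS(geno)
        sidx <- sampleIds(similarity)
        if (!all(ids %in% sidx))
            stop("similarity matrix missing ids: ",
                 paste(setdiff(ids, sidx), collapse = ", "))
        A <- similarityValues(similarity)[ids, ids]
        offsets <- precomputeOffsets(A, y, center = center, encoding = encoding)
    } else {
        offsets <- rep(0, length(y))
    }

    Z <- .prepareSnpColumns(G)
    rows <- lapply(seq_len(ncol(Z)), function(j)
        testSnp(Z[, j], XBase, y, offsets, snpId = colnames(G)[j],
                coupling = coupling, optimizer = optimizer, eta = eta,
                tol = tol, maxIter = maxIter, encoding = encoding))
    tab <- do.call(rbind, rows)
    rownames(tab) <- NULL
    meta <- list(n = length(y), m = ncol(G),
                 covariates = colnames(XBase)[-1],
                 mafMin = mafMin, missingMax = missingMax,
                 coupling = coupling, center = center,
                 optimizer = optimizer, eta = eta, tol = tol,
                 maxIter = as.integer(maxIter), encoding = encoding,
                 offsetOps = attr(offsets, "ops"))
    new("ScanResult", table = tab, metadata = meta)
}
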