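#' @import methods
#' @importFrom stats median plogis pchisq qchisq qbeta rbinom rbeta runif
#'   rnorm sd uniroot ks.test quantile glm binomial coef vcov complete.cases
#' @importFrom utils read.table write.table
NULL

#' GenotypeMatrix: minor-allele count genotypes
#'
#' Stores an n individuals x m SNPs matrix of minor-allele counts.  Each
#' non-missing entry is 0, 1 or 2 (the number of copies of the minor allele
#' carried at that locus); missing genotypes are `NA`.  Individuals and SNPs
#' are keyed by character identifiers, and all joins elsewhere in the
#' package are id-based, never positional.
#'
#' @slot values integer matrix (n x m) with entries in \{0, 1, 2\} or `NA`;
#'   rownames are individual ids, colnames are SNP ids.
#' @export
setClass("GenotypeMatrix", representation(values = "matrix"))

setValidity("GenotypeMatrix", function(object) {
    v <- object@values
    if (!is.matrix(v)) return("values must be a matrix")
    if (nrow(v) < 2L) return("need at least 2 individuals")
    if (ncol(v) < 1L) return("need at least 1 SNP")
    if (is.null(rownames(v)) || is.null(colnames(v)))
        return("values must carry individual ids (rownames) and SNP ids (colnames)")
    if (anyDuplicated(rownames(v))) return("duplicated individual ids")
    obs <- v[!is.na(v)]
    if (length(obs) && !all(obs %in% c(0, 1, 2)))
        return("non-missing genotype entries must be 0, 1 or 2")
    TRUE
})

#' Construct a GenotypeMatrix
#'
#' @param values matrix of minor-allele counts (0/1/2, `NA` for missing).
#' @param individualIds,snpIds optional identifier vectors; taken from
#'   dimnames when omitted, generated (`ind1..`, `snp1..`) when absent.
#' @return a [GenotypeMatrix-class] object.
#' @examples
#' g <- GenotypeMatrix(matrix(c(0, 1, 2, 2, 1, 0), nrow = 2, byrow = TRUE))
#' genotypes(g)
#' @export
GenotypeMatrix <- function(values, individualIds = NULL, snpIds = NULL) {
    values <- as.matrix(values)
    storage.mode(values) <- "integer"
    if (is.null(individualIds))
        individualIds <- rownames(values)
    if (is.null(individualIds))
        individualIds <- paste0("ind", seq_len(nrow(values)))
    if (is.null(snpIds))
        snpIds <- colnames(values)
    if (is.null(snpIds))
        snpIds <- paste0("snp", seq_len(ncol(values)))
    dimnames(values) <- list(as.character(individualIds), as.character(snpIds))
    new("GenotypeMatrix", values = values)
}

#' SimilarityMatrix: pairwise genetic similarities
#'
#' Symmetric n x n matrix of pairwise genetic similarities (identity-by-state
#' allele-sharing fractions), entries in [0, 1] with unit diagonal.  The
#' diagonal is never used in any model sum; self-edges are excluded when
#' coupling offsets are formed.
#'
#' @slot values numeric symmetric matrix with unit diagonal; dimnames are
#'   individual ids.
#' @export
setClass("SimilarityMatrix", representation(values = "matrix"))

setValidity("SimilarityMatrix", function(object) {
    v <- object@values
    if (!is.matrix(v) || nrow(v) != ncol(v)) return("values must be square")
    if (is.null(rownames(v))) return("values must carry individual ids")
    if (!isTRUE(all.equal(v, t(v), tolerance = 1e-8, check.attributes = FALSE)))
        return("values must be symmetric")
    if (any(v < -1e-12 | v > 1 + 1e-12)) return("entries must lie in [0, 1]")
    if (any(abs(diag(v) - 1) > 1e-8)) return("diagonal must equal 1")
    TRUE
})

#' Construct a SimilarityMatrix
#'
#' @param values symmetric numeric matrix, entries in [0, 1], unit diagonal.
#' @param individualIds optional ids (defaults to rownames or `ind1..`).
#' @return a [SimilarityMatrix-class] object.
#' @export
SimilarityMatrix <- function(values, individualIds = NULL) {
    values <- as.matrix(values)
    if (is.null(individualIds)) individualIds <- rownames(values)
    if (is.null(individualIds)) individualIds <- paste0("ind", seq_len(nrow(values)))
    dimnames(values) <- list(as.character(individualIds), as.character(individualIds))
    values <- (values + t(values)) / 2
    new("SimilarityMatrix", values = values)
}

#' CovariateMatrix: per-individual covariates
#'
#' Numeric n x p covariate matrix.  When `standardized` is `TRUE` each
#' column has zero mean and unit (population) standard deviation to within
#' 1e-8, except columns that were constant in the input: these are mapped to
#' all-zeros and recorded in `constantColumns`.
#'
#' @slot values numeric matrix (n x p); rownames are individual ids.
#' @slot standardized logical flag.
#' @slot constantColumns character vector of column names zeroed because
#'   they carried no variation.
#' @export
setClass("CovariateMatrix",
    representation(values = "matrix", standardized = "logical",
                   constantColumns = "character"))

setValidity("CovariateMatrix", function(object) {
    v <- object@values
    if (!is.numeric(v)) return("values must be numeric")
    if (isTRUE(object@standardized) && ncol(v)) {
        live <- setdiff(colnames(v), object@constantColumns)
        for (nm in live) {
            x <- v[, nm]
            if (abs(mean(x)) > 1e-8) return(sprintf("column %s not centred", nm))
            if (abs(sqrt(mean((x - mean(x))^2)) - 1) > 1e-8)
                return(sprintf("column %s not unit-variance", nm))
        }
    }
    TRUE
})

#' Construct a CovariateMatrix
#'
#' @param values numeric matrix or data.frame of covariates.
#' @param individualIds optional individual ids.
#' @param standardized whether `values` are already column z-scores.
#' @param constantColumns names of columns zeroed during standardization.
#' @return a [CovariateMatrix-class] object.
#' @export
CovariateMatrix <- function(values, individualIds = NULL,
                            standardized = FALSE,
                            constantColumns = character()) {
    values <- as.matrix(values)
    storage.mode(values) <- "double"
    if (is.null(individualIds)) individualIds <- rownames(values)
    if (is.null(individualIds)) individualIds <- paste0("ind", seq_len(nrow(values)))
    if (is.null(colnames(values)) && ncol(values))
        colnames(values) <- paste0("cov", seq_len(ncol(values)))
    rownames(values) <- as.character(individualIds)
    new("CovariateMatrix", values = values, standardized = standardized,
        constantColumns = constantColumns)
}

#' CRFFit: a fitted pairwise conditional random field
#'
#' Result of minimising the negative log-pseudo-likelihood of the pairwise
#' phenotype CRF for one design matrix.  Holds the weight estimates, the
#' Hessian H and score outer-product B at the optimum, the sandwich variance
#' H^-1 B H^-1, and a convergence record.  `opCount` is an instrumentation
#' counter of data-touching floating point operations performed during the
#' iterations (used to verify the linear-per-iteration cost contract).
#'
#' @slot weights named numeric vector of estimated weights.
#' @slot negLogPL numeric, objective value at the optimum.
#' @slot gradient named numeric, gradient at the returned weights.
#' @slot hessian numeric matrix H.
#' @slot scoreOuter numeric matrix B.
#' @slot sandwich numeric matrix H^-1 B H^-1.
#' @slot iterations integer iteration count.
#' @slot converged logical.
#' @slot gradNorm numeric max-norm of the gradient at the returned weights.
#' @slot droppedColumns character, design columns removed as collinear.
#' @slot singularHessian logical, `TRUE` when H had to be pseudo-inverted.
#' @slot opCount numeric operation count accumulated over iterations.
#' @export
setClass("CRFFit",
    representation(weights = "numeric", negLogPL = "numeric",
                   gradient = "numeric", hessian = "matrix",
                   scoreOuter = "matrix", sandwich = "matrix",
                   iterations = "integer", converged = "logical",
                   gradNorm = "numeric", droppedColumns = "character",
                   singularHessian = "logical", opCount = "numeric"))

#' ScanResult: per-SNP association scan results
#'
#' One row per tested SNP with the estimated SNP weight, robust standard
#' error, Wald chi-square statistic and p-value.  Untestable SNPs (constant
#' column, collinear with covariates, non-converged fit or singular Hessian)
#' are flagged with `converged = FALSE` and `NA` statistics, never dropped.
#'
#' @slot table data.frame with columns snp_id, beta, se, chi2, p, converged.
#' @slot metadata list of run settings (sample size, covariate names,
#'   coupling mode, optimizer settings, seed where applicable).
#' @export
setClass("ScanResult", representation(table = "data.frame", metadata = "list"))

setValidity("ScanResult", function(object) {
    need <- c("snp_id", "beta", "se", "chi2", "p", "converged")
    if (!all(need %in% names(object@table)))
        return(paste("table must have columns", paste(need, collapse = ", ")))
    p <- object@table$p
    if (any(!is.na(p) & (p < 0 | p > 1))) return("p-values must lie in [0, 1]")
    TRUE
})

#' SyntheticDataset: a simulated study with known ground truth
#'
#' Bundles simulated genotypes, covariates, GLMM-sampled binary phenotypes,
#' the similarity matrix used as the random-effect covariance, and the true
#' per-SNP regression weights (non-zero exactly for the causal SNPs).
#'
#' @slot genotypes a [GenotypeMatrix-class].
#' @slot covariates a [CovariateMatrix-class] (possibly 0 columns).
#' @slot phenotypes named integer vector of 0/1 labels.
#' @slot similarity a [SimilarityMatrix-class].
#' @slot truth named numeric vector of true SNP weights (0 for null SNPs).
#' @slot config list of generator settings (seeds included).
#' @export
setClass("SyntheticDataset",
    representation(genotypes = "GenotypeMatrix",
                   covariates = "CovariateMatrix",
                   phenotypes = "integer",
                   similarity = "SimilarityMatrix",
                   truth = "numeric", config = "list"))

setValidity("SyntheticDataset", function(object) {
    y <- object@phenotypes
    if (!all(y %in% c(0L, 1L))) return("phenotypes must be 0/1")
    if (length(y) != nrow(object@genotypes@values))
        return("phenotype length must match genotype rows")
    if (length(object@truth) != ncol(object@genotypes@values))
        return("truth must have one entry per SNP")
    TRUE
})
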