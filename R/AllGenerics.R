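#' Accessors for package classes
#'
#' `genotypes()` returns the integer minor-allele-count matrix;
#' `missingMask()` the logical missingness mask; `snpIds()` and
#' `sampleIds()` the identifier vectors; `similarityValues()` and
#' `covariateValues()` the underlying numeric matrices;
#' `isStandardized()`/`constantColumns()` the standardization record;
#' `resultsTable()`/`scanMetadata()` the scan output; `phenotypes()` and
#' `trueWeights()` the simulated labels and ground-truth SNP weights;
#' `sandwichVariance()`, `converged()` and `gradNorm()` the fit record.
#'
#' @param x,object an object of the documented class.
#' @return the slot content described above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))
#' @rdname accessors
#' @export
setGeneric("missingMask", function(x) standardGeneric("missingMask"))
#' @rdname accessors
#' @export
setGeneric("snpIds", function(x) standardGeneric("snpIds"))
#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname accessors
#' @export
setGeneric("similarityValues", function(x) standardGeneric("similarityValues"))
#' @rdname accessors
#' @export
setGeneric("covariateValues", function(x) standardGeneric("covariateValues"))
#' @rdname accessors
#' @export
setGeneric("isStandardized", function(x) standardGeneric("isStandardized"))
#' @rdname accessors
#' @export
setGeneric("constantColumns", function(x) standardGeneric("constantColumns"))
#' @rdname accessors
#' @export
setGeneric("resultsTable", function(x) standardGeneric("resultsTable"))
#' @rdname accessors
#' @export
setGeneric("scanMetadata", function(x) standardGeneric("scanMetadata"))
#' @rdname accessors
#' @export
setGeneric("phenotypes", function(x) standardGeneric("phenotypes"))
#' @rdname accessors
#' @export
setGeneric("trueWeights", function(x) standardGeneric("trueWeights"))
#' @rdname accessors
#' @export
setGeneric("sandwichVariance", function(x) standardGeneric("sandwichVariance"))
#' @rdname accessors
#' @export
setGeneric("converged", function(x) standardGeneric("converged"))
#' @rdname accessors
#' @export
setGeneric("gradNorm", function(x) standardGeneric("gradNorm"))

#' @rdname accessors
setMethod("genotypes", "GenotypeMatrix", function(x) x@values)
#' @rdname accessors
setMethod("missingMask", "GenotypeMatrix", function(x) is.na(x@values))
#' @rdname accessors
setMethod("snpIds", "GenotypeMatrix", function(x) colnames(x@values))
#' @rdname accessors
setMethod("sampleIds", "GenotypeMatrix", function(x) rownames(x@values))
#' @rdname accessors
setMethod("sampleIds", "SimilarityMatrix", function(x) rownames(x@values))
#' @rdname accessors
setMethod("sampleIds", "CovariateMatrix", function(x) rownames(x@values))
#' @rdname accessors
setMethod("similarityValues", "SimilarityMatrix", function(x) x@values)
#' @rdname accessors
setMethod("covariateValues", "CovariateMatrix", function(x) x@values)
#' @rdname accessors
setMethod("isStandardized", "CovariateMatrix", function(x) x@standardized)
#' @rdname accessors
setMethod("constantColumns", "CovariateMatrix", function(x) x@constantColumns)
#' @rdname accessors
setMethod("resultsTable", "ScanResult", function(x) x@table)
#' @rdname accessors
setMethod("scanMetadata", "ScanResult", function(x) x@metadata)
#' @rdname accessors
setMethod("genotypes", "SyntheticDataset", function(x) x@genotypes)
#' @rdname accessors
setMethod("phenotypes", "SyntheticDataset", function(x) x@phenotypes)
#' @rdname accessors
setMethod("trueWeights", "SyntheticDataset", function(x) x@truth)
#' @rdname accessors
setMethod("similarityValues", "SyntheticDataset",
          function(x) x@similarity@values)
#' @rdname accessors
setMethod("sandwichVariance", "CRFFit", function(x) x@sandwich)
#' @rdname accessors
setMethod("converged", "CRFFit", function(x) x@converged)
#' @rdname accessors
setMethod("gradNorm", "CRFFit", function(x) x@gradNorm)

#' @rdname accessors
#' @export
setMethod("weights", "CRFFit", function(object) object@weights)

#' @export
setMethod("as.matrix", "GenotypeMatrix", function(x, ...) x@values)
#' @export
setMethod("as.matrix", "SimilarityMatrix", function(x, ...) x@values)
#' @export
setMethod("as.matrix", "CovariateMatrix", function(x, ...) x@values)

#' @export
as.data.frame.ScanResult <- function(x, ...) x@table

setMethod("show", "GenotypeMatrix", function(object) {
    v <- object@values
    cat(sprintf("GenotypeMatrix: %d individuals x %d SNPs (%.2f%% missing)\n",
                nrow(v), ncol(v), 100 * mean(is.na(v))))
})

setMethod("show", "SimilarityMatrix", function(object) {
    v <- object@values
    off <- v[upper.tri(v)]
    cat(sprintf("SimilarityMatrix: %d individuals, off-diagonal range [%.3f, %.3f], mean %.3f\n",
                nrow(v), min(off), max(off), mean(off)))
})

setMethod("show", "CovariateMatrix", function(object) {
    cat(sprintf("CovariateMatrix: %d individuals x %d covariates%s\n",
                nrow(object@values), ncol(object@values),
                if (object@standardized) " (standardized)" else ""))
    if (length(object@constantColumns))
        cat("  constant columns zeroed:",
            paste(object@constantColumns, collapse = ", "), "\n")
})

setMethod("show", "CRFFit", function(object) {
    cat(sprintf("CRFFit: %d weights, -log PL = %.4f, %d iterations, %s (|grad| = %.2e)\n",
                length(object@weights), object@negLogPL, object@iterations,
                if (object@converged) "converged" else "NOT converged",
                object@gradNorm))
})

setMethod("show", "ScanResult", function(object) {
    tab <- object@table
    cat(sprintf("ScanResult: %d SNPs tested (%d flagged untestable)\n",
                nrow(tab), sum(!tab$converged)))
    print(utils::head(tab, 5), row.names = FALSE)
    if (nrow(tab) > 5) cat("  ...\n")
})

setMethod("show", "SyntheticDataset", function(object) {
    cat(sprintf("SyntheticDataset: n = %d, m = %d, prevalence %.3f, %d causal SNP(s)\n",
                length(object@phenotypes), length(object@truth),
                mean(object@phenotypes), sum(object@truth != 0)))
})
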