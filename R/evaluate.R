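# Calibration and discrimination metrics: genomic inflation factor,
# KS uniformity, QQ data with order-statistic bounds, ROC/AUC against
# known simulation truth.

# median of the chi-square distribution with 1 df, fixed to 8 significant
# digits so lambda values are bit-comparable across runs
.CHISQ1_MEDIAN <- 0.45493642

#' Genomic inflation factor
#'
#' `lambda = median(chi2) / 0.45493642`, the observed median association
#' statistic relative to the median of the chi-square distribution with
#' one degree of freedom.  Values near 1 indicate calibrated tests;
#' `lambda > 1` signals inflation, the signature of unmodelled population
#' or family structure.  Computed from Wald statistics directly rather
#' than round-tripping through p-values.
#'
#' @param chi2Stats numeric vector of Wald chi-square statistics
#'   (non-finite entries are dropped).
#' @return the inflation factor, a positive number.
#' @export
genomicInflation <- function(chi2Stats) {
    chi2Stats <- chi2Stats[is.finite(chi2Stats)]
    if (!length(chi2Stats)) stop("no finite statistics supplied")
    median(chi2Stats) / .CHISQ1_MEDIAN
}

#' One-sample Kolmogorov-Smirnov test against Uniform(0, 1)
#'
#' @param pValues numeric vector of p-values in [0, 1].
#' @return list with elements `statistic` and `p.value`.
#' @export
ksUniformity <- function(pValues) {
    pValues <- pValues[!is.na(pValues)]
    if (!length(pValues)) stop("no p-values supplied")
    if (any(pValues < 0 | pValues > 1)) stop("p-values must lie in [0, 1]")
    kt <- suppressWarnings(ks.test(pValues, "punif"))
    list(statistic = unname(kt$statistic), p.value = unname(kt$p.value))
}

#' QQ data for -log10 p-values
#'
#' Pairs the sorted observed `-log10 p` with the expected quantiles
#' `-log10((k - 0.5) / n)` for rank k, together with pointwise 95%
#' bounds from the beta distribution of uniform order statistics
#' (`Beta(k, n + 1 - k)`).  Zero p-values are clamped to the smallest
#' positive double with a warning.
#'
#' @param pValues numeric vector of p-values in (0, 1].
#' @return data.frame with columns `expected`, `observed`, `lower`,
#'   `upper` (all on the -log10 scale), ordered from most to least
#'   significant.
#' @export
qqData <- function(pValues) {
    pValues <- pValues[!is.na(pValues)]
    if (!length(pValues)) stop("no p-values supplied")
    if (any(pValues == 0)) {
        warning("zero p-values clamped to .Machine$double.xmin")
        pValues[pValues == 0] <- .Machine$double.xmin
    }
    n <- length(pValues)
    k <- seq_len(n)
    data.frame(expected = -log10((k - 0.5) / n),
               observed = -log10(sort(pValues)),
               lower = -log10(qbeta(0.975, k, n + 1 - k)),
               upper = -log10(qbeta(0.025, k, n + 1 - k)))
}

#' ROC curve and AUC from null and alternative p-values
#'
#' Sweeps the significance level over every distinct p-value; at each
#' level alpha the false positive rate is the fraction of null-SNP
#' p-values <= alpha and the true positive rate the fraction of causal-SNP
#' p-values <= alpha.  The AUC is the trapezoidal integral of the curve
#' and equals the Mann-Whitney probability that a random causal SNP
#' receives a smaller p-value than a random null SNP (ties counted 1/2).
#'
#' @param pNull p-values of SNPs simulated with zero weight.
#' @param pAlt p-values of SNPs simulated with non-zero weight.
#' @return list with `thresholds`, `fpr`, `tpr` (each including the
#'   (0, 0) and (1, 1) endpoints) and `auc`.
#' @export
rocAuc <- function(pNull, pAlt) {
    pNull <- pNull[!is.na(pNull)]
    pAlt <- pAlt[!is.na(pAlt)]
    if (!length(pNull) || !length(pAlt))
        stop("both null and alternative p-values are required")
    thr <- sort(unique(c(pNull, pAlt)))
    fpr <- vapply(thr, function(a) mean(pNull <= a), numeric(1))
    tpr <- vapply(thr, function(a) mean(pAlt <= a), numeric(1))
    fpr <- c(0, fpr)
    tpr <- c(0, tpr)
    if (fpr[length(fpr)] < 1 || tpr[length(tpr)] < 1) {
        fpr <- c(fpr, 1)
        tpr <- c(tpr, 1)
        thr <- c(thr, Inf)
    }
    auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
    list(thresholds = c(-Inf, thr), fpr = fpr, tpr = tpr, auc = auc)
}

#' Scan a benchmark collection
#'
#' Runs the association scan over a [buildBenchmark()] collection.  Null
#' datasets (all true weights zero) are scanned in full, providing the
#' null p-value pool, the inflation factor and the KS uniformity check;
#' for non-null datasets only the causal SNP is tested by default (its
#' p-value is the power observation for that replicate), since the
#' coupling offsets must be re-derived for each dataset's phenotypes
#' anyway.
#'
#' @param benchmark list of [SyntheticDataset-class] from
#'   [buildBenchmark()].
#' @param altOnly test only the causal SNP in non-null datasets
#'   (default `TRUE`).
#' @param ... further arguments passed to [runScan()]/[testSnp()]
#'   (e.g. `coupling = "none"` for the naive logistic comparator).
#' @return data.frame with columns `beta`, `rep`, `snp_id`, `p`, `chi2`,
#'   `isCausal`.
#' @export
scanBenchmark <- function(benchmark, altOnly = TRUE, ...) {
    dots <- list(...)
    rows <- lapply(benchmark, function(ds) {
        beta <- ds@config$beta
        y <- phenotypes(ds)
        if (beta == 0 || !altOnly) {
            scan <- do.call(runScan, c(list(geno = genotypes(ds), pheno = y,
                                            similarity = ds@similarity), dots))
            tab <- resultsTable(scan)
            data.frame(beta = beta, rep = ds@config$rep, snp_id = tab$snp_id,
                       p = tab$p, chi2 = tab$chi2,
                       isCausal = trueWeights(ds)[tab$snp_id] != 0,
                       stringsAsFactors = FALSE)
        } else {
            causal <- ds@config$causal
            G <- genotypes(genotypes(ds))
            Z <- .prepareSnpColumns(G)
            coupling <- if (!is.null(dots$coupling)) dots$coupling else "fitted"
            center <- if (!is.null(dots$center)) dots$center else TRUE
            offsets <- if (coupling == "none") rep(0, length(y)) else
                precomputeOffsets(similarityValues(ds), y, center = center)
            XBase <- matrix(1, length(y), 1,
                            dimnames = list(names(y), "intercept"))
            res <- testSnp(Z[, causal], XBase, y, offsets,
                           snpId = colnames(G)[causal], coupling = coupling)
            data.frame(beta = beta, rep = ds@config$rep, snp_id = res$snp_id,
                       p = res$p, chi2 = res$chi2, isCausal = TRUE,
                       stringsAsFactors = FALSE)
        }
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Evaluate a scanned benchmark
#'
#' Summarises [scanBenchmark()] output: genomic inflation factor and KS
#' uniformity on the null (beta = 0) p-values, and for each non-zero
#' weight the ROC/AUC of its causal-SNP p-values against the null pool.
#' Requires beta = 0 runs (the false-positive reference).
#'
#' @param scans data.frame from [scanBenchmark()].
#' @return list with `lambda_null`, `ks_null` (statistic and p.value),
#'   `n_null`, and `auc` -- a data.frame with columns `beta`, `auc`,
#'   `n_alt`.
#' @export
evaluateBenchmark <- function(scans) {
    nulls <- scans[scans$beta == 0 & !scans$isCausal & !is.na(scans$p), ]
    if (!nrow(nulls)) stop("no beta = 0 runs: no false-positive reference")
    betas <- sort(setdiff(unique(scans$beta), 0))
    aucTab <- do.call(rbind, lapply(betas, function(b) {
        pa <- scans$p[scans$beta == b & scans$isCausal & !is.na(scans$p)]
        if (!length(pa)) {
            warning("no testable causal SNP at beta = ", b, "; AUC is NA")
            return(data.frame(beta = b, auc = NA_real_, n_alt = 0L))
        }
        data.frame(beta = b, auc = rocAuc(nulls$p, pa)$auc, n_alt = length(pa))
    }))
    list(lambda_null = genomicInflation(nulls$chi2),
         ks_null = ksUniformity(nulls$p),
         n_null = nrow(nulls),
         auc = aucTab)
}
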