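# Readers and writers: PLINK text .ped/.map, a TSV genotype matrix
# dialect (header row of SNP ids, first column the individual id),
# phenotype/covariate TSV tables keyed by individual id, similarity-matrix
# TSV, scan-result TSV with a '#'-prefixed config header, and JSON
# reports.  Readers validate and reject malformed input rather than
# silently coercing.

#' Read genotypes from PLINK text or TSV
#'
#' `format = "ped"` parses a white-space delimited PLINK text fileset:
#' `path` is the `.ped` (six leading columns, then two allele columns per
#' SNP; `0` denotes a missing allele) and `mapPath` the matching `.map`
#' (chromosome, SNP id, genetic distance, position).  Alleles are recoded
#' to minor-allele counts, the minor allele being the less frequent
#' allele in the sample (ties broken lexicographically).  `format = "tsv"`
#' reads the matrix dialect written by [writeGenotypes()]: a header of
#' SNP ids, first column the individual id, entries 0/1/2 or NA.
#' `format = "auto"` picks by file extension.
#'
#' @param path input file.
#' @param format `"auto"`, `"tsv"` or `"ped"`.
#' @param mapPath `.map` path (defaults to `path` with its extension
#'   replaced by `.map`).
#' @return a [GenotypeMatrix-class].
#' @export
readGenotypes <- function(path, format = c("auto", "tsv", "ped"),
                          mapPath = NULL) {
    format <- match.arg(format)
    if (format == "auto")
        format <- if (grepl("\\.ped$", path, ignore.case = TRUE)) "ped" else "tsv"
    if (format == "tsv") return(.readGenotypesTsv(path))
    .readGenotypesPed(path, mapPath)
}

.readGenotypesTsv <- function(path) {
    tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                      colClasses = "character", comment.char = "#")
    if (ncol(tab) < 2) stop("genotype TSV needs an id column and >= 1 SNP")
    ids <- tab[[1]]
    vals <- as.matrix(tab[, -1, drop = FALSE])
    suppressWarnings(storage.mode(vals) <- "integer")
    bad <- which(!is.na(as.matrix(tab[, -1, drop = FALSE])) &
                 !(as.matrix(tab[, -1, drop = FALSE]) %in% c("0", "1", "2", "NA")))
    if (length(bad))
        stop("non-genotype value in TSV at matrix position ", bad[1])
    GenotypeMatrix(vals, individualIds = ids, snpIds = colnames(vals))
}

.readGenotypesPed <- function(path, mapPath = NULL) {
    if (is.null(mapPath)) mapPath <- sub("\\.ped$", ".map", path)
    if (!file.exists(mapPath)) stop("missing .map file: ", mapPath)
    map <- read.table(mapPath, header = FALSE, colClasses = "character")
    if (ncol(map) < 2) stop("malformed .map: need at least 2 columns")
    snps <- map[[2]]
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    n <- length(lines)
    if (!n) stop("empty .ped file")
    m <- length(snps)
    alleles <- matrix(NA_character_, n, 2L * m)
    ids <- character(n)
    for (li in seq_len(n)) {
        f <- strsplit(trimws(lines[li]), "[ \t]+")[[1]]
        if (length(f) != 6L + 2L * m)
            stop(sprintf("malformed .ped line %d: %d fields, expected %d",
                         li, length(f), 6L + 2L * m))
        ids[li] <- f[2]
        alleles[li, ] <- f[-(1:6)]
    }
    known <- c("A", "C", "G", "T", "1", "2", "3", "4", "0")
    if (!all(alleles %in% known))
        stop("unknown allele symbol(s): ",
             paste(unique(setdiff(alleles, known)), collapse = ", "))
    G <- matrix(NA_integer_, n, m)
    for (j in seq_len(m)) {
        a1 <- alleles[, 2L * j - 1L]
        a2 <- alleles[, 2L * j]
        miss <- a1 == "0" | a2 == "0"
        obs <- c(a1[!miss], a2[!miss])
        if (!length(obs)) next
        counts <- table(obs)
        lev <- names(sort(counts))          # ascending count, names sorted
        minor <- lev[1]
        if (length(lev) > 1 && counts[lev[1]] == counts[lev[2]])
            minor <- min(lev[1], lev[2])    # tie: lexicographic
        G[, j] <- (a1 == minor) + (a2 == minor)
        G[miss, j] <- NA_integer_
    }
    GenotypeMatrix(G, individualIds = ids, snpIds = snps)
}

#' Write genotypes as the TSV matrix dialect
#'
#' @param geno a [GenotypeMatrix-class].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeGenotypes <- function(geno, path) {
    G <- genotypes(geno)
    df <- data.frame(id = rownames(G), G, check.names = FALSE,
                     stringsAsFactors = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a binary phenotype table
#'
#' Expects a TSV with a header containing an id column and a phenotype
#' column.  Values 0/1 are taken as-is; 1/2 (the PLINK case/control
#' convention, with 2 = case) are remapped to 0/1 with a message.  Any
#' other value is an error naming the offending ids.
#'
#' @param path input TSV.
#' @param idColumn id column name (default first column).
#' @param column phenotype column name (default second column).
#' @return named integer 0/1 vector.
#' @export
readPhenotypes <- function(path, idColumn = NULL, column = NULL) {
    tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                      comment.char = "#", stringsAsFactors = FALSE)
    if (ncol(tab) < 2) stop("phenotype TSV needs id and phenotype columns")
    if (is.null(idColumn)) idColumn <- names(tab)[1]
    if (is.null(column)) column <- setdiff(names(tab), idColumn)[1]
    ids <- as.character(tab[[idColumn]])
    y <- tab[[column]]
    if (all(y %in% c(0, 1))) {
        y <- as.integer(y)
    } else if (all(y %in% c(1, 2))) {
        message("phenotype coded 1/2; remapping to 0/1 (2 = case)")
        y <- as.integer(y) - 1L
    } else {
        bad <- ids[!(y %in% c(0, 1, 2))]
        stop("non-binary phenotype values for ids: ",
             paste(utils::head(bad, 10), collapse = ", "))
    }
    names(y) <- ids
    y
}

#' Read a covariate table
#'
#' TSV with header; the first (or named) column is the individual id, the
#' remaining numeric columns are covariates.
#'
#' @param path input TSV.
#' @param idColumn id column name (default first column).
#' @return a [CovariateMatrix-class] (not yet standardized).
#' @export
readCovariates <- function(path, idColumn = NULL) {
    tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                      comment.char = "#", stringsAsFactors = FALSE)
    if (is.null(idColumn)) idColumn <- names(tab)[1]
    ids <- as.character(tab[[idColumn]])
    v <- as.matrix(tab[, setdiff(names(tab), idColumn), drop = FALSE])
    if (!is.numeric(v)) stop("covariate columns must be numeric")
    CovariateMatrix(v, individualIds = ids)
}

#' Write / read a similarity matrix as TSV
#'
#' TSV with the individual ids as both header row and first column.
#'
#' @param sim a [SimilarityMatrix-class].
#' @param path file path.
#' @return `writeSimilarity` invisibly returns `path`; `readSimilarity`
#'   returns a [SimilarityMatrix-class].
#' @export
writeSimilarity <- function(sim, path) {
    v <- similarityValues(sim)
    df <- data.frame(id = rownames(v), v, check.names = FALSE,
                     stringsAsFactors = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeSimilarity
#' @export
readSimilarity <- function(path) {
    tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                      comment.char = "#", stringsAsFactors = FALSE)
    ids <- as.character(tab[[1]])
    v <- as.matrix(tab[, -1, drop = FALSE])
    if (!identical(colnames(v), ids))
        stop("similarity TSV header ids do not match row ids")
    SimilarityMatrix(v, individualIds = ids)
}

#' Write / read scan results
#'
#' Writes the per-SNP table as TSV preceded by a '#'-prefixed comment
#' block embedding the run metadata as JSON, so every run is reproducible
#' from its own output.  Untestable SNPs are serialized with empty
#' statistic fields, never omitted.  P-values keep at least 6 significant
#' digits.
#'
#' @param scan a [ScanResult-class].
#' @param path file path.
#' @param adjust optional multiple-testing adjustment appended as an
#'   extra column: `"bonferroni"` or `"BH"` (default none; the core scan
#'   reports raw p-values).
#' @return `writeScanResults` invisibly returns `path`;
#'   `readScanResults` returns a [ScanResult-class].
#' @export
writeScanResults <- function(scan, path, adjust = NULL) {
    tab <- resultsTable(scan)
    if (!is.null(adjust)) {
        adjust <- match.arg(adjust, c("bonferroni", "BH"))
        tab[[paste0("p_", adjust)]] <- stats::p.adjust(tab$p, method = adjust)
    }
    num <- vapply(tab, is.numeric, logical(1))
    out <- tab
    for (j in which(num)) out[[j]] <- signif(tab[[j]], 8)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("# crfgwas scan results"), con)
    writeLines(paste0("# config: ",
                      jsonlite::toJSON(scanMetadata(scan), auto_unbox = TRUE,
                                       digits = NA)), con)
    suppressWarnings(write.table(out, con, sep = "\t", quote = FALSE,
                                 row.names = FALSE, na = ""))
    invisible(path)
}

#' @rdname writeScanResults
#' @export
readScanResults <- function(path) {
    lines <- readLines(path)
    hdr <- grep("^#", lines, value = TRUE)
    meta <- list()
    cfg <- grep("^# config: ", hdr, value = TRUE)
    if (length(cfg))
        meta <- jsonlite::fromJSON(sub("^# config: ", "", cfg[1]))
    tab <- read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                      sep = "\t", stringsAsFactors = FALSE,
                      na.strings = c("NA", ""))
    tab$converged <- as.logical(tab$converged)
    new("ScanResult", table = tab, metadata = as.list(meta))
}

#' Write an evaluation report as JSON (plus optional TSV point tables)
#'
#' @param report list from [evaluateBenchmark()], or any serializable
#'   report structure.
#' @param path output `.json` path.
#' @return invisibly, `path`.
#' @export
writeReport <- function(report, path) {
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(path)
}
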