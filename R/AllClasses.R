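#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay assayNames rowData colData
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom stats rbeta rbinom rpois sd var setNames complete.cases
#' @importFrom utils read.delim write.table packageVersion
NULL

#' PoolCounts: per-site, per-pool read counts from pooled sequencing
#'
#' `PoolCounts` extends [SummarizedExperiment::SummarizedExperiment] with
#' three integer assays — `depth`, `refReads` and `altReads` — holding, for
#' every variant site (row) and every pooled accession (column), the total
#' read depth and the reads supporting the reference and alternate alleles.
#' Site metadata (chromosome, 1-based position, alleles, variant class,
#' biallelic flag) live in `rowData`; the lineage assignment of each pool
#' (accession, crop type, species) lives in `colData` once a
#' [LineageHierarchy] has been attached.
#'
#' The class invariant is `refReads + altReads == depth` with all counts
#' non-negative; a depth of zero is a legal value meaning the site was not
#' observed in that pool (it becomes `MISSING` downstream).
#'
#' @slot  (inherited) assays, rowData, colData from SummarizedExperiment.
#' @seealso [PoolCounts()] the constructor, [readPoolVcf()], [filterSites()]
#' @export
setClass("PoolCounts", contains = "SummarizedExperiment")

setValidity("PoolCounts", function(object) {
    msg <- character()
    an <- SummarizedExperiment::assayNames(object)
    need <- c("depth", "refReads", "altReads")
    if (!all(need %in% an))
        return(paste("assays must include", paste(need, collapse = ", ")))
    d <- SummarizedExperiment::assay(object, "depth")
    r <- SummarizedExperiment::assay(object, "refReads")
    a <- SummarizedExperiment::assay(object, "altReads")
    if (any(d < 0, na.rm = TRUE) || any(r < 0, na.rm = TRUE) ||
        any(a < 0, na.rm = TRUE))
        msg <- c(msg, "read counts must be non-negative")
    if (!isTRUE(all(r + a == d)))
        msg <- c(msg, "refReads + altReads must equal depth at every cell")
    rd <- SummarizedExperiment::rowData(object)
    needCols <- c("chrom", "pos", "ref", "alt", "variantClass", "biallelic")
    if (!all(needCols %in% colnames(rd)))
        msg <- c(msg, paste("rowData must contain",
                            paste(needCols, collapse = ", ")))
    else {
        if (any(rd$pos < 1)) msg <- c(msg, "positions are 1-based (>= 1)")
        if (any(!nzchar(rd$ref))) msg <- c(msg, "ref alleles must be non-empty")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a PoolCounts object
#'
#' @param depth,refReads,altReads integer matrices, sites x pools, with
#'   identical dimensions and `refReads + altReads == depth`.
#' @param variantTable data.frame with one row per site and columns `chrom`,
#'   `pos` (1-based), `ref`, `alt` (comma-separated if several), and
#'   optionally `variantClass` and `biallelic` (computed from the alleles
#'   when absent).
#' @param poolIds character vector of pool (accession) identifiers; defaults
#'   to the column names of `depth`.
#' @return A [PoolCounts] object.
#' @examples
#' vt <- data.frame(chrom = "chr1", pos = 1:2, ref = "A", alt = "T")
#' d <- matrix(10L, 2, 2, dimnames = list(NULL, c("p1", "p2")))
#' pc <- PoolCounts(d, d - 3L, matrix(3L, 2, 2), vt)
#' pc
#' @export
PoolCounts <- function(depth, refReads, altReads, variantTable,
                       poolIds = colnames(depth)) {
    depth <- as.matrix(depth); refReads <- as.matrix(refReads)
    altReads <- as.matrix(altReads)
    if (!all(dim(depth) == dim(refReads)) || !all(dim(depth) == dim(altReads)))
        stop("count matrices must share dimensions")
    if (is.null(poolIds)) poolIds <- paste0("pool", seq_len(ncol(depth)))
    dimnames(depth) <- dimnames(refReads) <- dimnames(altReads) <-
        list(NULL, poolIds)
    vt <- as.data.frame(variantTable)
    if (nrow(vt) != nrow(depth))
        stop("variantTable rows must match count matrix rows")
    if (is.null(vt$variantClass))
        vt$variantClass <- classifyVariant(vt$ref, vt$alt)
    if (is.null(vt$biallelic))
        vt$biallelic <- lengths(strsplit(as.character(vt$alt), ",",
                                         fixed = TRUE)) == 1L
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(depth = depth, refReads = refReads, altReads = altReads),
        rowData = S4Vectors::DataFrame(vt),
        colData = S4Vectors::DataFrame(row.names = poolIds))
    new("PoolCounts", se)
}

#' Lineage hierarchy of pooled accessions
#'
#' A three-level partition of the sequenced pools: every pool is one
#' accession, every accession belongs to exactly one crop type, and all crop
#' types belong to one species. Used to aggregate diversity, classify
#' lineage-specific variation, and define AMOVA strata.
#'
#' @slot table data.frame with columns `pool_id`, `accession`, `crop_type`,
#'   `species`, one row per pool.
#' @seealso [readHierarchy()], [validateHierarchy()]
#' @export
setClass("LineageHierarchy", representation(table = "data.frame"))

setValidity("LineageHierarchy", function(object) {
    tb <- object@table
    need <- c("pool_id", "accession", "crop_type", "species")
    if (!all(need %in% colnames(tb)))
        return(paste("hierarchy table needs columns",
                     paste(need, collapse = ", ")))
    if (nrow(tb) == 0L) return("hierarchy is empty")
    msg <- character()
    dup <- unique(tb$pool_id[duplicated(tb$pool_id)])
    if (length(dup))
        msg <- c(msg, paste("pool(s) assigned more than once:",
                            paste(dup, collapse = ", ")))
    accCt <- unique(tb[, c("accession", "crop_type")])
    dupAcc <- unique(accCt$accession[duplicated(accCt$accession)])
    if (length(dupAcc))
        msg <- c(msg, paste("accession(s) in more than one crop type:",
                            paste(dupAcc, collapse = ", ")))
    if (length(unique(tb$species)) != 1L)
        msg <- c(msg, "exactly one species label expected")
    if (length(msg)) msg else TRUE
})

#' Construct a LineageHierarchy from a data.frame
#'
#' @param table data.frame with columns `pool_id`, `accession`, `crop_type`,
#'   `species` (species may be omitted; a single placeholder is filled in).
#' @return A validated [LineageHierarchy].
#' @export
LineageHierarchy <- function(table) {
    tb <- as.data.frame(table, stringsAsFactors = FALSE)
    if (is.null(tb$species)) tb$species <- "species"
    for (cc in c("pool_id", "accession", "crop_type", "species"))
        if (!is.null(tb[[cc]])) tb[[cc]] <- as.character(tb[[cc]])
    new("LineageHierarchy", table = tb)
}

#' Ground truth of a hierarchical pool-seq simulation
#'
#' Holds the latent allele frequencies at each level of the hierarchy
#' (ancestral, crop type, accession), the bookkeeping of deliberately
#' injected lineage-specific variants, the chromosome assignment of the
#' loci, the generating parameters and the matching [LineageHierarchy].
#'
#' @slot ancestralFreqs numeric vector, one ancestral frequency per locus.
#' @slot cropTypeFreqs matrix, crop types x loci.
#' @slot accessionFreqs matrix, accessions x loci.
#' @slot injectedLSV data.frame (locus, lineage, level) of injected private
#'   fixed variants; zero rows when none were injected.
#' @slot chrom character vector of chromosome labels per locus.
#' @slot pos integer vector of 1-based positions per locus.
#' @slot params the `SimParams` list used.
#' @slot hierarchy the matching [LineageHierarchy].
#' @seealso [simulateFrequencies()], [injectLSV()], [samplePoolCounts()]
#' @export
setClass("PoolSimTruth", representation(
    ancestralFreqs = "numeric",
    cropTypeFreqs  = "matrix",
    accessionFreqs = "matrix",
    injectedLSV    = "data.frame",
    chrom          = "character",
    pos            = "integer",
    params         = "list",
    hierarchy      = "LineageHierarchy"))

setValidity("PoolSimTruth", function(object) {
    msg <- character()
    allf <- c(object@ancestralFreqs, object@cropTypeFreqs,
              object@accessionFreqs)
    if (any(allf < 0 | allf > 1))
        msg <- c(msg, "all frequencies must lie in [0, 1]")
    L <- length(object@ancestralFreqs)
    if (ncol(object@cropTypeFreqs) != L || ncol(object@accessionFreqs) != L)
        msg <- c(msg, "frequency matrices must have one column per locus")
    if (length(object@chrom) != L || length(object@pos) != L)
        msg <- c(msg, "chrom/pos must have one entry per locus")
    if (length(msg)) msg else TRUE
})

setMethod("show", "PoolCounts", function(object) {
    cat("PoolCounts:", nrow(object), "sites x", ncol(object), "pools\n")
    rd <- SummarizedExperiment::rowData(object)
    cat("  variant classes:",
        paste(sprintf("%s=%d", names(table(rd$variantClass)),
                      as.integer(table(rd$variantClass))), collapse = " "),
        "\n")
    cat("  biallelic sites:", sum(rd$biallelic), "\n")
    d <- SummarizedExperiment::assay(object, "depth")
    cat("  mean depth:", round(mean(d), 1), "\n")
    invisible(NULL)
})

setMethod("show", "LineageHierarchy", function(object) {
    tb <- object@table
    cat("LineageHierarchy:", unique(tb$species), "\n")
    sz <- table(tb$crop_type)
    cat(" ", length(sz), "crop types (",
        paste(sprintf("%s: %d", names(sz), as.integer(sz)), collapse = ", "),
        "),", nrow(tb), "pools\n")
    invisible(NULL)
})

setMethod("show", "PoolSimTruth", function(object) {
    cat("PoolSimTruth:", length(object@ancestralFreqs), "loci,",
        nrow(object@accessionFreqs), "accessions in",
        nrow(object@cropTypeFreqs), "crop types;",
        nrow(object@injectedLSV), "injected LSV\n")
    invisible(NULL)
})

#' Site metadata of a PoolCounts object
#'
#' @param x A [PoolCounts] object.
#' @return data.frame with chromosome, position, alleles, variant class and
#'   biallelic flag, one row per site.
#' @export
variantTable <- function(x) {
    as.data.frame(SummarizedExperiment::rowData(x))
}

#' Pool identifiers of a hierarchy, in table order
#' @param h A [LineageHierarchy].
#' @return Character vector of pool ids.
#' @export
poolIds <- function(h) h@table$pool_id

#' Unique crop-type labels of a hierarchy
#' @param h A [LineageHierarchy].
#' @return Character vector.
#' @export
cropTypes <- function(h) unique(h@table$crop_type)

#' Unique accession labels of a hierarchy
#' @param h A [LineageHierarchy].
#' @return Character vector.
#' @export
accessions <- function(h) unique(h@table$accession)

#' The hierarchy as a plain data.frame
#' @param h A [LineageHierarchy].
#' @return data.frame with pool_id, accession, crop_type, species.
#' @export
hierarchyTable <- function(h) h@table

#' Pools belonging to a lineage
#'
#' @param h A [LineageHierarchy].
#' @param lineage Lineage label.
#' @param level One of `"accession"`, `"crop_type"`, `"species"`.
#' @return Character vector of pool ids inside the lineage.
#' @export
poolsOf <- function(h, lineage, level = c("accession", "crop_type", "species")) {
    level <- match.arg(level)
    tb <- h@table
    key <- switch(level, accession = tb$accession,
                  crop_type = tb$crop_type, species = tb$species)
    valid <- unique(key)
    if (!lineage %in% valid)
        stop("unknown ", level, " '", lineage, "'; valid: ",
             paste(valid, collapse = ", "))
    tb$pool_id[key == lineage]
}

#' Injected lineage-specific variant records of a simulation truth
#' @param truth A [PoolSimTruth].
#' @return data.frame with locus, lineage, level.
#' @export
injectedLSV <- function(truth) truth@injectedLSV
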