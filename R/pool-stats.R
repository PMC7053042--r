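#' Pooled alternate-allele frequencies
#'
#' Estimates, per site and pool, the alternate-allele frequency
#' `q = altReads / depth`, with `p = 1 - q` anchored to the reference
#' genome's allele. Cells whose depth falls below `minDepth` are `NA`
#' (missing); a depth of zero never raises a division error.
#'
#' @param pc A [PoolCounts], normally after [filterSites()].
#' @param minDepth Depth below which a cell is treated as missing
#'   (default 15).
#' @return Numeric matrix, sites x pools, of q in \[0, 1\] with `NA` for
#'   missing cells.
#' @examples
#' tr <- simulateFrequencies(simParams(nLoci = 50, seed = 1))
#' fm <- alleleFrequency(samplePoolCounts(tr, seed = 1))
#' range(fm, na.rm = TRUE)
#' @export
alleleFrequency <- function(pc, minDepth = 15) {
    d <- SummarizedExperiment::assay(pc, "depth")
    a <- SummarizedExperiment::assay(pc, "altReads")
    q <- ifelse(d >= pmax(minDepth, 1), a / d, NA_real_)
    dimnames(q) <- list(NULL, colnames(pc))
    q
}

#' Gene diversity (expected heterozygosity, 2pq)
#'
#' Computes per-site, per-pool gene diversity `2 p q` and its per-pool mean
#' over non-missing sites. `2pq` peaks at 0.5 when q = 0.5 and vanishes for
#' sites fixed for either allele; the per-pool mean summarizes the genetic
#' variation held within a pooled accession.
#'
#' @param fm Frequency matrix from [alleleFrequency()].
#' @return A list of class `"DiversityTable"` with `siteDiversity` (matrix,
#'   sites x pools) and `poolSummary` (data.frame: `pool`, `mean2pq`,
#'   `nSites`). Pools with no non-missing site get `NA` and are flagged via
#'   `nSites = 0`.
#' @examples
#' geneDiversity(matrix(c(0.5, 0, 1, 0.25), 2, 2))$poolSummary
#' @export
geneDiversity <- function(fm) {
    h <- 2 * fm * (1 - fm)
    nSites <- colSums(!is.na(h))
    m <- colMeans(h, na.rm = TRUE)
    m[nSites == 0L] <- NA_real_
    pools <- colnames(fm)
    if (is.null(pools)) pools <- paste0("pool", seq_len(ncol(fm)))
    out <- list(siteDiversity = h,
                poolSummary = data.frame(pool = pools, mean2pq = unname(m),
                                         nSites = unname(nSites),
                                         stringsAsFactors = FALSE))
    class(out) <- "DiversityTable"
    out
}

#' @export
print.DiversityTable <- function(x, ...) {
    cat("DiversityTable:", nrow(x$siteDiversity), "sites\n")
    print(x$poolSummary, row.names = FALSE)
    invisible(x)
}

#' Aggregate per-pool diversity by lineage
#'
#' Summarizes per-pool mean 2pq values as mean +/- sample standard
#' deviation over the member pools of each lineage at the requested level
#' (`species` aggregates all pools). An exclusion set allows removing
#' pools — e.g. highly inbred or self-fertile accessions — whose near-zero
#' diversity would distort a lineage mean.
#'
#' @param values A `DiversityTable` from [geneDiversity()], or a named
#'   numeric vector of per-pool values.
#' @param h A [LineageHierarchy] covering the pools.
#' @param level `"crop_type"` (default), `"accession"` or `"species"`.
#' @param exclude Character vector of pool ids to drop before aggregating.
#' @return data.frame with `lineage`, `mean`, `sd` (`NA` when fewer than two
#'   members remain), `n`.
#' @examples
#' vals <- c(a = 0.221, b = 0.202)
#' h <- LineageHierarchy(data.frame(pool_id = c("a", "b"),
#'     accession = c("a", "b"), crop_type = "fodder", species = "beet"))
#' aggregateByLineage(vals, h)
#' @export
aggregateByLineage <- function(values, h,
                               level = c("crop_type", "accession", "species"),
                               exclude = character()) {
    level <- match.arg(level)
    if (inherits(values, "DiversityTable"))
        values <- setNames(values$poolSummary$mean2pq,
                           values$poolSummary$pool)
    tb <- hierarchyTable(h)
    tb <- tb[tb$pool_id %in% names(values) & !(tb$pool_id %in% exclude), ,
             drop = FALSE]
    key <- switch(level, accession = tb$accession,
                  crop_type = tb$crop_type, species = tb$species)
    lineages <- unique(key)
    res <- lapply(lineages, function(ln) {
        v <- values[tb$pool_id[key == ln]]
        data.frame(lineage = ln, mean = mean(v),
                   sd = if (length(v) >= 2) sd(v) else NA_real_,
                   n = length(v), stringsAsFactors = FALSE)
    })
    do.call(rbind, res)
}

#' Export a frequency matrix as TSV
#'
#' Sites as rows (chromosome and position as the leading columns when a
#' [PoolCounts] is supplied), pools as columns — the conventional shape of a
#' pool-seq allele frequency matrix.
#'
#' @param fm Frequency matrix from [alleleFrequency()].
#' @param path Output path.
#' @param pc Optional [PoolCounts] providing site coordinates.
#' @return Invisibly, `path`.
#' @export
writeFrequencyMatrix <- function(fm, path, pc = NULL) {
    df <- as.data.frame(fm)
    if (!is.null(pc)) {
        vt <- variantTable(pc)
        df <- cbind(chrom = vt$chrom, pos = vt$pos, df)
    }
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
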