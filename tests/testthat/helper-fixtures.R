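# Shared fixture builders; everything is generated in code.

# Four pools, two crop types (A,B | C,D), one pool per accession.
fourPoolHierarchy <- function() {
    LineageHierarchy(data.frame(
        pool_id = c("A", "B", "C", "D"),
        accession = c("A", "B", "C", "D"),
        crop_type = c("ct1", "ct1", "ct2", "ct2"),
        species = "sp", stringsAsFactors = FALSE))
}

# Small PoolCounts with hand-set counts (sites x pools matrices).
toyPoolCounts <- function(depth, alt, chrom = NULL, ref = "A", altAllele = "T") {
    depth <- as.matrix(depth); alt <- as.matrix(alt)
    n <- nrow(depth)
    if (is.null(chrom)) chrom <- rep("chr1", n)
    vt <- data.frame(chrom = chrom, pos = seq_len(n) * 10L,
                     ref = rep(ref, length.out = n),
                     alt = rep(altAllele, length.out = n),
                     stringsAsFactors = FALSE)
    PoolCounts(depth, depth - alt, alt, vt,
               poolIds = colnames(depth) %||%
                   LETTERS[seq_len(ncol(depth))])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Path to a published-table fixture shipped with the package.
extdata <- function(f) system.file("extdata", f, package = "poolDiversity",
                                   mustWork = TRUE)

# The beet hierarchy (23 pools, crop types 10/7/2/4).
beetHierarchy <- function() readHierarchy(extdata("beet_hierarchy.tsv"))
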