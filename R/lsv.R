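.STATES <- c("ABSENT", "SEGREGATING", "FIXED", "MISSING")

#' Discretize pool frequencies into allele states
#'
#' Maps each frequency to `ABSENT` (q <= epsilon), `FIXED`
#' (q >= 1 - epsilon) or `SEGREGATING` (otherwise); missing cells propagate
#' as `MISSING`. With noise-free counts epsilon = 0 is exact; with real read
#' counts a small epsilon (e.g. 0.05) absorbs the binomial sampling noise
#' that makes exact 0/1 frequencies rare at finite depth.
#'
#' @param fm Frequency matrix from [alleleFrequency()].
#' @param epsilon Tolerance in \[0, 0.5).
#' @return Character matrix, sites x pools, of states.
#' @examples
#' poolState(matrix(c(0, 0.5, 1, NA), 1), epsilon = 0)
#' @export
poolState <- function(fm, epsilon = 0) {
    if (epsilon < 0 || epsilon >= 0.5)
        stop("epsilon must lie in [0, 0.5)")
    st <- matrix("SEGREGATING", nrow(fm), ncol(fm),
                 dimnames = dimnames(fm))
    st[!is.na(fm) & fm <= epsilon] <- "ABSENT"
    st[!is.na(fm) & fm >= 1 - epsilon] <- "FIXED"
    st[is.na(fm)] <- "MISSING"
    st
}

#' Discretize VCF genotype calls into allele states
#'
#' Mirrors a genotype-call based private-variant scan: homozygous-reference
#' calls (or no call of the alternate) map to `ABSENT`, homozygous-alternate
#' to `FIXED`, heterozygous to `SEGREGATING`, and missing calls (`./.`) to
#' `MISSING`.
#'
#' @param gt Character matrix of VCF `GT` strings (as stored in
#'   `metadata(pc)$genotypes` by [readPoolVcf()]).
#' @return Character matrix of states with the same shape.
#' @export
poolStateFromGenotypes <- function(gt) {
    g <- gsub("|", "/", as.matrix(gt), fixed = TRUE)
    st <- matrix("SEGREGATING", nrow(g), ncol(g), dimnames = dimnames(g))
    st[g %in% c("0/0", "0")] <- "ABSENT"
    st[g %in% c("1/1", "1")] <- "FIXED"
    st[is.na(g) | g %in% c("./.", ".", "./0", "0/.")] <- "MISSING"
    st
}

#' Classify lineage-specific variation (LSV)
#'
#' A site is LSV for a lineage L at a given level when the alternate allele
#' is fixed in every pool inside L and absent from every pool outside L —
#' homozygous private variation, an apomorphy of L. At the species level the
#' outside set is empty, so the condition reduces to fixation in all pools.
#'
#' Missing data are handled by `missingPolicy`: under `"strict"` (default) a
#' `MISSING` pool anywhere disqualifies the site for L (a pool inside L must
#' be demonstrably fixed, a pool outside demonstrably absent); under
#' `"lenient"` a `MISSING` pool outside L counts as absent.
#'
#' @param psm State matrix from [poolState()] or
#'   [poolStateFromGenotypes()].
#' @param h A [LineageHierarchy]; its pools must match the matrix columns.
#' @param level `"accession"`, `"crop_type"` or `"species"`.
#' @param missingPolicy `"strict"` or `"lenient"`.
#' @return Logical matrix, sites x lineages at that level, with the level
#'   stored in `attr(, "level")`.
#' @examples
#' h <- LineageHierarchy(data.frame(pool_id = c("A", "B", "C", "D"),
#'     accession = c("A", "B", "C", "D"),
#'     crop_type = c("ct1", "ct1", "ct2", "ct2"), species = "sp"))
#' psm <- matrix(c("FIXED", "ABSENT", "ABSENT", "ABSENT"), 1,
#'               dimnames = list(NULL, c("A", "B", "C", "D")))
#' classifyLSV(psm, h, "accession")
#' @export
classifyLSV <- function(psm, h,
                        level = c("accession", "crop_type", "species"),
                        missingPolicy = c("strict", "lenient")) {
    level <- match.arg(level)
    missingPolicy <- match.arg(missingPolicy)
    tb <- hierarchyTable(h)
    if (is.null(colnames(psm)))
        colnames(psm) <- tb$pool_id
    if (!all(tb$pool_id %in% colnames(psm)))
        stop("state matrix lacks pools: ",
             paste(setdiff(tb$pool_id, colnames(psm)), collapse = ", "))
    fx <- psm == "FIXED"
    ab <- psm == "ABSENT"
    if (missingPolicy == "lenient")
        abOut <- ab | psm == "MISSING"
    else abOut <- ab
    key <- switch(level, accession = tb$accession,
                  crop_type = tb$crop_type, species = tb$species)
    lineages <- unique(key)
    flags <- vapply(lineages, function(ln) {
        inside <- tb$pool_id[key == ln]
        outside <- setdiff(tb$pool_id, inside)
        ok <- rowSums(fx[, inside, drop = FALSE]) == length(inside)
        if (length(outside))
            ok <- ok & rowSums(abOut[, outside, drop = FALSE]) ==
                length(outside)
        ok
    }, logical(nrow(psm)))
    flags <- matrix(flags, nrow(psm), length(lineages),
                    dimnames = list(NULL, lineages))
    attr(flags, "level") <- level
    flags
}

#' Tally lineage-specific variation by class and chromosome
#'
#' @param flags Logical site x lineage matrix from [classifyLSV()].
#' @param vt Variant table (data.frame with `chrom` and `variantClass`)
#'   aligned to the rows of `flags`; a [PoolCounts] is also accepted.
#' @param chromosomes Chromosome labels defining column order; defaults to
#'   the order of appearance in `vt$chrom`.
#' @return A list of class `"LsvReport"`: `summary` (data.frame lineage,
#'   level, total, snp, indel, chromMean = total / number of chromosomes)
#'   and `byChromosome` (lineage x chromosome count matrix).
#' @examples
#' # see classifyLSV() for constructing flags
#' @export
lsvReport <- function(flags, vt, chromosomes = NULL) {
    if (is(vt, "PoolCounts")) vt <- variantTable(vt)
    if (nrow(vt) != nrow(flags))
        stop("flags and variant table are not aligned")
    if (is.null(chromosomes)) chromosomes <- unique(vt$chrom)
    lineages <- colnames(flags)
    byChrom <- t(vapply(lineages, function(ln) {
        tab <- table(factor(vt$chrom[flags[, ln]], levels = chromosomes))
        as.integer(tab)
    }, integer(length(chromosomes))))
    dimnames(byChrom) <- list(lineages, chromosomes)
    isSnp <- vt$variantClass %in% c("SNP", "multiallelic_SNP")
    summ <- data.frame(
        lineage = lineages,
        level = rep(attr(flags, "level") %||% NA_character_,
                    length(lineages)),
        total = colSums(flags),
        snp = vapply(lineages, function(ln) sum(flags[, ln] & isSnp),
                     numeric(1)),
        indel = vapply(lineages, function(ln)
            sum(flags[, ln] & vt$variantClass == "indel"), numeric(1)),
        stringsAsFactors = FALSE, row.names = NULL)
    summ$chromMean <- summ$total / length(chromosomes)
    out <- list(summary = summ, byChromosome = byChrom)
    class(out) <- "LsvReport"
    out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.LsvReport <- function(x, ...) {
    cat("LsvReport (", ncol(x$byChromosome), "chromosomes )\n")
    print(x$summary, row.names = FALSE)
    invisible(x)
}

#' Export per-site LSV flags as a BED-like table
#'
#' @param flags Logical matrix from [classifyLSV()].
#' @param vt Variant table (or [PoolCounts]) aligned to `flags`.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
writeLsvSites <- function(flags, vt, path) {
    if (is(vt, "PoolCounts")) vt <- variantTable(vt)
    idx <- which(flags, arr.ind = TRUE)
    df <- data.frame(chrom = vt$chrom[idx[, 1]], pos = vt$pos[idx[, 1]],
                     lineage = colnames(flags)[idx[, 2]],
                     level = attr(flags, "level") %||% NA_character_)
    df <- df[order(df$chrom, df$pos), ]
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
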