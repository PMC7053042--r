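#' Classify variants from their alleles
#'
#' A site is a `SNP` when the reference and its single alternate allele are
#' both one base; `multiallelic_SNP` when several single-base alternates
#' exist; `indel` when any alternate differs in length from the reference;
#' `other` covers the remainder (e.g. multi-base substitutions).
#'
#' @param ref Character vector of reference alleles.
#' @param alt Alternate alleles: a character vector (comma-separated when a
#'   site has several) or a list of character vectors, parallel to `ref`.
#' @return Character vector of classes, one per site.
#' @examples
#' classifyVariant("A", "T")
#' classifyVariant(c("A", "C"), c("AT", "T,G"))
#' @export
classifyVariant <- function(ref, alt) {
    ref <- as.character(ref)
    altList <- if (is.list(alt)) lapply(alt, as.character)
               else strsplit(as.character(alt), ",", fixed = TRUE)
    if (length(altList) != length(ref))
        stop("ref and alt must be parallel")
    vapply(seq_along(ref), function(i) {
        r <- ref[i]; a <- altList[[i]]
        if (!nzchar(r) || any(!nzchar(a)) || length(a) == 0L)
            stop("empty allele string at site ", i)
        if (any(nchar(a) != nchar(r))) return("indel")
        if (nchar(r) == 1L) {
            if (length(a) == 1L) return("SNP")
            return("multiallelic_SNP")
        }
        "other"
    }, character(1))
}

## Sum allelic depths into (depth, ref, alt) triples; NA -> unobserved (0).
.adToCounts <- function(adCell) {
    v <- suppressWarnings(as.integer(adCell))
    if (length(v) == 0L || all(is.na(v))) return(c(0L, 0L))
    v[is.na(v)] <- 0L
    c(v[1], sum(v[-1]))
}

#' Read pooled allele counts from a multi-sample VCF
#'
#' Parses a VCF v4.2 (plain or gzip-compressed) with one sample column per
#' pooled accession and builds a [PoolCounts] from the per-sample allelic
#' depths. The `AD` FORMAT field is preferred; `RO`/`AO` observation counts
#' are used as a fallback when `AD` is absent. Records without either get
#' depth 0 in every pool (treated as missing downstream). For multiallelic
#' records the alternate count is the sum over alternate alleles and the
#' biallelic flag is `FALSE`; such sites are normally removed by
#' [filterSites()]. Genotype calls (`GT`), when present, are kept in
#' `metadata(x)$genotypes` for the genotype-call discretization mode.
#'
#' @param path Path to the VCF file.
#' @return A [PoolCounts].
#' @seealso [writePoolVcf()], [filterSites()]
#' @export
readPoolVcf <- function(path) {
    vcf <- VariantAnnotation::readVcf(path)
    n <- length(vcf)
    samp <- rownames(SummarizedExperiment::colData(vcf))
    k <- length(samp)
    gn <- VariantAnnotation::geno(vcf)
    if ("AD" %in% names(gn)) {
        ad <- gn$AD
        ref <- matrix(0L, n, k); altc <- matrix(0L, n, k)
        for (j in seq_len(k)) {
            cc <- vapply(ad[, j], .adToCounts, integer(2))
            ref[, j] <- cc[1, ]; altc[, j] <- cc[2, ]
        }
        source <- "AD"
    } else if (all(c("RO", "AO") %in% names(gn))) {
        ref <- gn$RO; ref[is.na(ref)] <- 0L
        ao <- gn$AO
        altc <- if (is.list(ao[1, 1]))
            matrix(vapply(ao, function(v) sum(as.integer(v), na.rm = TRUE),
                          integer(1)), n, k)
        else { ao[is.na(ao)] <- 0L; ao }
        source <- "RO/AO"
    } else {
        stop("VCF has neither AD nor RO/AO per-sample count fields")
    }
    depth <- ref + altc
    rr <- SummarizedExperiment::rowRanges(vcf)
    altSet <- VariantAnnotation::alt(vcf)
    altStr <- vapply(as(altSet, "CharacterList"), paste, character(1),
                     collapse = ",")
    vt <- data.frame(
        chrom = as.character(GenomeInfoDb::seqnames(rr)),
        pos = BiocGenerics::start(rr),
        ref = as.character(VariantAnnotation::ref(vcf)),
        alt = altStr, stringsAsFactors = FALSE)
    pc <- PoolCounts(depth, ref, altc, vt, poolIds = samp)
    S4Vectors::metadata(pc)$countSource <- source
    message("allele counts taken from per-sample ", source, " field")
    if ("GT" %in% names(gn))
        S4Vectors::metadata(pc)$genotypes <- gn$GT
    pc
}

#' Write a PoolCounts object as a VCF v4.2 file
#'
#' Emits one record per site with `GT:AD:DP` per sample (genotype `./.`
#' throughout — pooled samples have no diploid genotype), so that
#' [readPoolVcf()] round-trips counts, positions and alleles exactly.
#'
#' @param pc A [PoolCounts].
#' @param path Output path (plain text).
#' @return Invisibly, `path`.
#' @export
writePoolVcf <- function(pc, path) {
    vt <- variantTable(pc)
    d <- SummarizedExperiment::assay(pc, "depth")
    r <- SummarizedExperiment::assay(pc, "refReads")
    a <- SummarizedExperiment::assay(pc, "altReads")
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(
        "##fileformat=VCFv4.2",
        "##source=poolDiversity",
        "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
        "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref,alt)\">",
        "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
        paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                "INFO", "FORMAT", colnames(pc)), collapse = "\t")), con)
    geno <- matrix(sprintf("./.:%d,%d:%d", r, a, d), nrow(pc), ncol(pc))
    lines <- paste(vt$chrom, vt$pos, ".", vt$ref, vt$alt, ".", "PASS", ".",
                   "GT:AD:DP",
                   apply(geno, 1, paste, collapse = "\t"), sep = "\t")
    writeLines(lines, con)
    invisible(path)
}

#' Filter sites on depth, biallelic status and variant class
#'
#' Keeps sites at which every pool reaches the minimum read depth
#' (default 15), that are biallelic when `biallelicOnly`, and whose class is
#' in `classes`. Order is preserved and the operation is idempotent.
#'
#' @param pc A [PoolCounts].
#' @param minDepth Minimum depth required in every pool (default 15).
#' @param biallelicOnly Keep only biallelic sites (default `TRUE`).
#' @param classes Variant classes to keep (default `"SNP"`; use
#'   `c("SNP", "indel")` to keep indels too, or `NULL` for all classes).
#' @return The filtered [PoolCounts].
#' @examples
#' tr <- simulateFrequencies(simParams(nLoci = 100, seed = 1))
#' pc <- samplePoolCounts(tr, seed = 1)
#' nrow(filterSites(pc, minDepth = 15))
#' @export
filterSites <- function(pc, minDepth = 15, biallelicOnly = TRUE,
                        classes = "SNP") {
    if (minDepth < 0) stop("minDepth must be non-negative")
    d <- SummarizedExperiment::assay(pc, "depth")
    vt <- variantTable(pc)
    keep <- rowSums(d >= minDepth) == ncol(d)
    if (biallelicOnly) keep <- keep & vt$biallelic
    if (!is.null(classes)) keep <- keep & vt$variantClass %in% classes
    pc[keep, ]
}

#' Read a lineage hierarchy from TSV or JSON
#'
#' The TSV form has header columns `pool_id`, `accession`, `crop_type`,
#' `species`; the JSON form is an array of objects with the same keys (or a
#' single object of those column arrays). Partition invariants — each pool
#' in exactly one accession, each accession in exactly one crop type — are
#' enforced at construction.
#'
#' @param path Path to a `.tsv`/`.txt` or `.json` file.
#' @return A [LineageHierarchy].
#' @export
readHierarchy <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    if (file.size(path) == 0) stop("hierarchy file is empty: ", path)
    if (grepl("\\.json$", path, ignore.case = TRUE)) {
        tb <- as.data.frame(jsonlite::fromJSON(path))
    } else {
        tb <- read.delim(path, stringsAsFactors = FALSE)
    }
    if (nrow(tb) == 0L) stop("hierarchy file has no rows: ", path)
    LineageHierarchy(tb)
}

#' Cross-check a hierarchy against pooled count data
#'
#' @param h A [LineageHierarchy].
#' @param pc A [PoolCounts] (or anything with `colnames`).
#' @return A list with `missingFromHierarchy` (pools present in the counts
#'   but not the hierarchy), `missingFromCounts` (the converse) and `ok`.
#' @export
validateHierarchy <- function(h, pc) {
    pools <- colnames(pc)
    hp <- poolIds(h)
    out <- list(missingFromHierarchy = setdiff(pools, hp),
                missingFromCounts = setdiff(hp, pools))
    out$ok <- length(out$missingFromHierarchy) == 0L &&
        length(out$missingFromCounts) == 0L
    out
}
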