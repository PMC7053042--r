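#' Run the pooled diversity pipeline end to end
#'
#' Orchestrates the full analysis: read (or accept) pooled counts and the
#' lineage hierarchy, filter sites, estimate frequencies, then compute gene
#' diversity with lineage summaries, the hierarchical lineage-specific
#' variation report, the shared-variation relationship matrix with a
#' bootstrapped neighbor-joining tree, allele-frequency PCA and AMOVA.
#' Identical inputs and seed yield an identical bundle; the run manifest
#' records every parameter.
#'
#' @param counts A [PoolCounts], or `NULL` to read `vcf`.
#' @param hierarchy A [LineageHierarchy] or a path readable by
#'   [readHierarchy()].
#' @param vcf Path to a multi-pool VCF (used when `counts` is `NULL`).
#' @param minDepth All-pool depth filter and missing threshold (default 15).
#' @param classes Variant classes kept for frequency-based stages
#'   (default `c("SNP", "indel")`; the LSV tallies split them again).
#' @param epsilon Frequency tolerance for allele-state discretization.
#' @param minAltReads Presence threshold for shared-variation counting.
#' @param coefficient Relationship coefficient for the tree
#'   (`"dice"`, `"cosine"` or `"king_pseudo"`).
#' @param nBootstrap Bootstrap replicates for branch support (default 100).
#' @param nPerm AMOVA permutations (0 disables the test).
#' @param excludeFromDiversity Pools dropped from lineage diversity means.
#' @param missingPolicy Missing handling for the LSV scan.
#' @param seed Integer seed covering bootstrap and permutations.
#' @param outputDir Optional directory; when given, all tables are written
#'   as TSV, the tree as newick, and the manifest as JSON.
#' @return A list of class `"ReportBundle"` with elements
#'   `diversity` (per-pool and per-lineage tables), `lsv` (per-level
#'   [lsvReport()] results), `sharedCounts`, `relationship`,
#'   `relationshipTable`, `tree`, `pca`, `amova`, `amovaPermutation`
#'   (or `NULL`), and `manifest`.
#' @export
runPipeline <- function(counts = NULL, hierarchy, vcf = NULL,
                        minDepth = 15, classes = c("SNP", "indel"),
                        epsilon = 0.05, minAltReads = 2,
                        coefficient = c("dice", "cosine", "king_pseudo"),
                        nBootstrap = 100, nPerm = 0,
                        excludeFromDiversity = character(),
                        missingPolicy = "strict",
                        seed = 1L, outputDir = NULL) {
    coefficient <- match.arg(coefficient)
    if (is.null(counts)) {
        if (is.null(vcf)) stop("supply either counts or a vcf path")
        counts <- readPoolVcf(vcf)
    }
    h <- if (is(hierarchy, "LineageHierarchy")) hierarchy
         else readHierarchy(hierarchy)
    chk <- validateHierarchy(h, counts)
    if (!chk$ok)
        stop("hierarchy validation failed; missing from hierarchy: [",
             paste(chk$missingFromHierarchy, collapse = ", "),
             "]; missing from counts: [",
             paste(chk$missingFromCounts, collapse = ", "), "]")
    counts <- counts[, poolIds(h)]

    filtered <- filterSites(counts, minDepth = minDepth,
                            biallelicOnly = TRUE, classes = classes)
    message("filterSites: ", nrow(counts), " -> ", nrow(filtered), " sites")
    fm <- alleleFrequency(filtered, minDepth = minDepth)
    vt <- variantTable(filtered)

    div <- geneDiversity(fm)
    divByCt <- aggregateByLineage(div, h, "crop_type",
                                  exclude = excludeFromDiversity)
    divSpecies <- aggregateByLineage(div, h, "species",
                                     exclude = excludeFromDiversity)

    psm <- poolState(fm, epsilon)
    lsv <- lapply(c(accession = "accession", crop_type = "crop_type",
                    species = "species"), function(lv) {
        lsvReport(classifyLSV(psm, h, lv, missingPolicy), vt,
                  chromosomes = unique(vt$chrom))
    })

    pres <- presenceMatrix(filtered, minAltReads)
    svm <- sharedVariantCounts(pres)
    rm <- if (coefficient == "king_pseudo") kingMatrix(pseudoGenotypes(fm))
          else relationshipCoefficients(svm, coefficient)
    bootInput <- if (coefficient == "king_pseudo") fm else pres
    tree <- bootstrapSupport(bootInput, coefficient, nReps = nBootstrap,
                             seed = seed)
    relTab <- relationshipTable(svm, if (coefficient == "king_pseudo")
        relationshipCoefficients(svm) else rm)

    snpOnly <- vt$variantClass == "SNP"
    pca <- poolPca(fm[snpOnly, , drop = FALSE])
    am <- poolAmova(fm[snpOnly, , drop = FALSE], h)
    amPerm <- if (nPerm > 0)
        amovaPermutation(fm[snpOnly, , drop = FALSE], h, nPerm, seed)
    else NULL

    manifest <- list(
        package = "poolDiversity",
        version = as.character(packageVersion("poolDiversity")),
        seed = seed, minDepth = minDepth, classes = classes,
        epsilon = epsilon, minAltReads = minAltReads,
        coefficient = coefficient, nBootstrap = nBootstrap, nPerm = nPerm,
        missingPolicy = missingPolicy,
        excludeFromDiversity = excludeFromDiversity,
        nSitesInput = nrow(counts), nSitesFiltered = nrow(filtered),
        nPools = ncol(counts))

    bundle <- list(diversity = list(perPool = div$poolSummary,
                                    byCropType = divByCt,
                                    species = divSpecies),
                   lsv = lsv, sharedCounts = svm, relationship = rm,
                   relationshipTable = relTab, tree = tree, pca = pca,
                   amova = am, amovaPermutation = amPerm,
                   manifest = manifest)
    class(bundle) <- "ReportBundle"
    if (!is.null(outputDir)) writeReportBundle(bundle, outputDir)
    bundle
}

#' Write a report bundle to a directory of plain-text files
#'
#' @param bundle A `"ReportBundle"` from [runPipeline()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
writeReportBundle <- function(bundle, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    w <- function(df, f) write.table(df, file.path(dir, f), sep = "\t",
                                     quote = FALSE, row.names = FALSE)
    w(bundle$diversity$perPool, "diversity_per_pool.tsv")
    w(bundle$diversity$byCropType, "diversity_by_crop_type.tsv")
    for (lv in names(bundle$lsv)) {
        w(bundle$lsv[[lv]]$summary, paste0("lsv_summary_", lv, ".tsv"))
        w(data.frame(lineage = rownames(bundle$lsv[[lv]]$byChromosome),
                     bundle$lsv[[lv]]$byChromosome, check.names = FALSE),
          paste0("lsv_by_chromosome_", lv, ".tsv"))
    }
    relationshipTable(bundle$sharedCounts,
                      if (attr(bundle$relationship, "method") == "king_pseudo")
                          relationshipCoefficients(bundle$sharedCounts)
                      else bundle$relationship,
                      file.path(dir, "relationship_matrix.tsv"))
    ape::write.tree(bundle$tree, file.path(dir, "nj_tree.nwk"))
    w(data.frame(pool = rownames(bundle$pca$scores),
                 bundle$pca$scores[, seq_len(min(5, ncol(bundle$pca$scores))),
                                   drop = FALSE]),
      "pca_scores.tsv")
    w(data.frame(component = seq_along(bundle$pca$varianceExplained),
                 varianceExplained = bundle$pca$varianceExplained),
      "pca_variance.tsv")
    w(bundle$amova$table, "amova.tsv")
    jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    invisible(dir)
}

#' Cross-table consistency checks for a report bundle
#'
#' Verifies the identities the published tables must satisfy: per-lineage
#' total LSV equals SNP plus indel LSV; per-lineage totals equal the sum of
#' chromosome counts; crop-type LSV totals sum to the species-level
#' crop-type-specific grand total; shared-variation off-diagonals never
#' exceed either diagonal; AMOVA percentages sum to 100.
#'
#' @param bundle A `"ReportBundle"` from [runPipeline()], or a list with
#'   any subset of the elements `lsv`, `sharedCounts`, `amova`.
#' @return Character vector of violation messages (empty when consistent).
#' @export
consistencyCheck <- function(bundle) {
    v <- character()
    for (lv in names(bundle$lsv)) {
        rep <- bundle$lsv[[lv]]
        s <- rep$summary
        bad <- s$lineage[s$total != s$snp + s$indel]
        if (length(bad))
            v <- c(v, paste0("LSV total != SNP + indel for ", lv, " ",
                             paste(bad, collapse = ", ")))
        chromSums <- rowSums(rep$byChromosome)[s$lineage]
        bad <- s$lineage[s$total != chromSums]
        if (length(bad))
            v <- c(v, paste0("LSV total != chromosome sum for ", lv, " ",
                             paste(bad, collapse = ", ")))
    }
    if (all(c("crop_type") %in% names(bundle$lsv)) &&
        !is.null(bundle$lsvCropTypeGrandTotal)) {
        tot <- sum(bundle$lsv$crop_type$summary$total)
        if (tot != bundle$lsvCropTypeGrandTotal)
            v <- c(v, sprintf(
                "crop-type LSV totals sum to %d, expected %d",
                tot, bundle$lsvCropTypeGrandTotal))
    }
    if (!is.null(bundle$sharedCounts)) {
        svm <- bundle$sharedCounts
        dg <- diag(svm)
        lim <- pmin(outer(dg, dg, pmin))
        if (any(svm > lim))
            v <- c(v, "shared-variation count exceeds a diagonal entry")
        if (!isTRUE(all.equal(svm, t(svm))))
            v <- c(v, "shared-variation matrix is not symmetric")
    }
    if (!is.null(bundle$amova)) {
        pct <- sum(bundle$amova$table$percent)
        if (abs(pct - 100) > 1e-6)
            v <- c(v, sprintf("AMOVA percentages sum to %.6f, not 100", pct))
    }
    v
}
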