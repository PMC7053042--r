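#' Principal component analysis of pool allele frequencies
#'
#' Sites with any missing pool are dropped (complete-case, matching the
#' all-pools depth filter), each locus is mean-centered across pools, and
#' the pools x sites matrix is factorized by singular value decomposition.
#' Scores are the pool coordinates `U D`; the variance explained by
#' component k is `d_k^2 / sum(d^2)`. No unit-variance scaling is applied,
#' so the geometry reflects the raw frequency covariance.
#'
#' @param fm Frequency matrix (sites x pools) from [alleleFrequency()].
#' @param center Mean-center each locus (default `TRUE`; centering is what
#'   makes variance-explained interpretable).
#' @param chrom Optional chromosome vector aligned to the rows of `fm`,
#'   required when `scope` is set.
#' @param scope Restrict the analysis to one chromosome label (default:
#'   genome-wide).
#' @return A list of class `"PcaResult"`: `scores` (pools x components),
#'   `varianceExplained`, `sdev`, `loadings`, `nSitesUsed`, `scope`.
#' @examples
#' tr <- simulateFrequencies(simParams(nLoci = 300, seed = 4))
#' fm <- alleleFrequency(samplePoolCounts(tr, seed = 4))
#' p <- poolPca(fm)
#' p$varianceExplained[1:2]
#' @export
poolPca <- function(fm, center = TRUE, chrom = NULL, scope = NULL) {
    if (!is.null(scope)) {
        if (is.null(chrom)) stop("scope requires a chromosome vector")
        fm <- fm[chrom == scope, , drop = FALSE]
    }
    fm <- fm[complete.cases(fm), , drop = FALSE]
    if (ncol(fm) < 2 || nrow(fm) < 2)
        stop("need at least 2 pools and 2 complete sites")
    x <- t(fm)
    if (center) x <- scale(x, center = TRUE, scale = FALSE)
    s <- svd(x)
    scores <- s$u %*% diag(s$d, length(s$d))
    rownames(scores) <- rownames(x)
    colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
    out <- list(scores = scores,
                varianceExplained = s$d^2 / sum(s$d^2),
                sdev = s$d / sqrt(max(nrow(x) - 1, 1)),
                loadings = s$v,
                nSitesUsed = nrow(fm),
                scope = scope %||% "genome")
    class(out) <- "PcaResult"
    out
}

#' @export
print.PcaResult <- function(x, ...) {
    cat("PcaResult (", x$scope, "):", x$nSitesUsed, "sites,",
        nrow(x$scores), "pools\n")
    ve <- round(100 * x$varianceExplained[seq_len(min(4,
        length(x$varianceExplained)))], 2)
    cat("  variance explained (%):", paste(ve, collapse = ", "), "...\n")
    invisible(x)
}

## Sums of squared Euclidean distances of rows to their mean vector.
.ssTo <- function(x, centre) sum(sweep(x, 2, centre)^2)

#' Hierarchical AMOVA for pooled allele frequencies
#'
#' Analysis of molecular variance on pool frequency vectors under the
#' squared-Euclidean metric: the total sum of squares over pools is
#' partitioned into among-crop-type, among-accession-within-crop-type and
#' within-accession (residual) strata, and variance components are obtained
#' from the mean squares with the standard weighted-n coefficients for
#' unequal group sizes. Negative components are truncated to zero before
#' percentages are formed. When every accession holds a single pool the
#' within-accession stratum has zero degrees of freedom; its component is
#' reported as 0 and flagged.
#'
#' @param fm Frequency matrix (sites x pools); sites with missing pools are
#'   dropped (complete-case).
#' @param h A [LineageHierarchy] covering the pools.
#' @return A list of class `"AmovaResult"` with `table` (data.frame:
#'   stratum, df, SS, MS, sigma, percent), `nSitesUsed`, and
#'   `flags` (character vector of degeneracy notes).
#' @examples
#' h <- LineageHierarchy(data.frame(
#'     pool_id = c("a1", "a2", "b1", "b2"),
#'     accession = c("a1", "a2", "b1", "b2"),
#'     crop_type = c("A", "A", "B", "B"), species = "sp"))
#' fm <- matrix(c(0, 0, 1, 1, 0, 0, 1, 1, 0.5, 0.5, 0.5, 0.5), 3, 4,
#'              byrow = TRUE, dimnames = list(NULL, c("a1", "a2", "b1", "b2")))
#' poolAmova(fm, h)$table
#' @export
poolAmova <- function(fm, h) {
    tb <- hierarchyTable(h)
    if (is.null(colnames(fm))) colnames(fm) <- tb$pool_id
    if (!all(tb$pool_id %in% colnames(fm)))
        stop("frequency matrix lacks pools named in the hierarchy")
    fm <- fm[complete.cases(fm), tb$pool_id, drop = FALSE]
    if (nrow(fm) < 1) stop("no complete sites for AMOVA")
    if (length(unique(tb$crop_type)) < 2)
        stop("AMOVA needs at least two crop types")
    x <- t(fm)                              # pools x loci observations
    N <- nrow(x)
    grand <- colMeans(x)
    flags <- character()

    ctOf <- tb$crop_type[match(rownames(x), tb$pool_id)]
    accOf <- tb$accession[match(rownames(x), tb$pool_id)]
    cts <- unique(ctOf); accs <- unique(accOf)
    g <- length(cts); a <- length(accs)
    nAccPools <- table(accOf)[accs]                    # pools per accession
    nCtPools <- table(ctOf)[cts]                       # pools per crop type
    accCt <- tb$crop_type[match(accs, tb$accession)]

    accMeans <- t(vapply(accs, function(ac)
        colMeans(x[accOf == ac, , drop = FALSE]), numeric(ncol(x))))
    ctMeans <- t(vapply(cts, function(ct)
        colMeans(x[ctOf == ct, , drop = FALSE]), numeric(ncol(x))))

    ssWithin <- sum(vapply(accs, function(ac)
        .ssTo(x[accOf == ac, , drop = FALSE], accMeans[ac, ]), numeric(1)))
    ssAcc <- sum(vapply(accs, function(ac)
        nAccPools[ac] * sum((accMeans[ac, ] - ctMeans[accCt[accs == ac], ])^2),
        numeric(1)))
    ssCt <- sum(vapply(cts, function(ct)
        nCtPools[ct] * sum((ctMeans[ct, ] - grand)^2), numeric(1)))

    dfCt <- g - 1; dfAcc <- a - g; dfWithin <- N - a
    ## Weighted-n coefficients for the nested design (unequal sizes)
    sumSqAccByCt <- sum(vapply(cts, function(ct) {
        inCt <- accs[accCt == ct]
        sum(nAccPools[inCt]^2) / nCtPools[ct]
    }, numeric(1)))
    n1 <- if (dfAcc > 0) (N - sumSqAccByCt) / dfAcc else NA_real_
    n2 <- (sumSqAccByCt - sum(nAccPools^2) / N) / dfCt
    n3 <- (N - sum(nCtPools^2) / N) / dfCt

    msWithin <- if (dfWithin > 0) ssWithin / dfWithin else NA_real_
    msAcc <- if (dfAcc > 0) ssAcc / dfAcc else NA_real_
    msCt <- ssCt / dfCt

    sigWithin <- if (dfWithin > 0) msWithin else {
        flags <- c(flags,
            "within-accession stratum has 0 df (one pool per accession); component reported 0")
        0
    }
    sigAcc <- if (dfAcc > 0) (msAcc - sigWithin) / n1 else {
        flags <- c(flags, "among-accession stratum has 0 df")
        0
    }
    sigCt <- (msCt - sigWithin - n2 * sigAcc) / n3

    raw <- c(sigCt, sigAcc, sigWithin)
    comp <- pmax(raw, 0)
    if (any(raw < 0))
        flags <- c(flags, "negative variance component truncated to 0")
    pct <- if (sum(comp) > 0) 100 * comp / sum(comp) else rep(0, 3)

    out <- list(table = data.frame(
        stratum = c("among_crop_types", "among_accessions_within_crop_types",
                    "within_accessions"),
        df = c(dfCt, dfAcc, dfWithin),
        SS = c(ssCt, ssAcc, ssWithin),
        MS = c(msCt, msAcc, msWithin),
        sigma = comp, percent = pct, stringsAsFactors = FALSE),
        nSitesUsed = ncol(x), flags = flags)
    class(out) <- "AmovaResult"
    out
}

#' @export
print.AmovaResult <- function(x, ...) {
    cat("AmovaResult:", x$nSitesUsed, "sites\n")
    print(transform(x$table, SS = signif(SS, 6), MS = signif(MS, 6),
                    sigma = signif(sigma, 6), percent = round(percent, 2)),
          row.names = FALSE)
    if (length(x$flags)) cat("  note:", paste(x$flags, collapse = "; "), "\n")
    invisible(x)
}

#' Permutation test for the among-crop-type AMOVA component
#'
#' Permutes the accession-to-crop-type assignment (keeping accession
#' membership of pools intact), recomputes the among-crop-type variance
#' component for each permutation, and reports
#' `p = (1 + #\{sigma_perm >= sigma_obs\}) / (nPerm + 1)`.
#'
#' @param fm Frequency matrix (sites x pools).
#' @param h A [LineageHierarchy].
#' @param nPerm Number of permutations (default 199).
#' @param seed Integer seed.
#' @return A list with `p.value`, `observed` (among-crop-type sigma),
#'   `permuted` (vector of permuted sigmas), `nPerm`.
#' @export
amovaPermutation <- function(fm, h, nPerm = 199, seed = 1L) {
    if (nPerm < 1) stop("nPerm must be >= 1")
    obs <- poolAmova(fm, h)$table$sigma[1]
    tb <- hierarchyTable(h)
    accs <- unique(tb$accession)
    accCt <- tb$crop_type[match(accs, tb$accession)]
    set.seed(seed)
    perm <- vapply(seq_len(nPerm), function(i) {
        newCt <- sample(accCt)
        tb2 <- tb
        tb2$crop_type <- newCt[match(tb$accession, accs)]
        poolAmova(fm, LineageHierarchy(tb2))$table$sigma[1]
    }, numeric(1))
    list(p.value = (1 + sum(perm >= obs)) / (nPerm + 1),
         observed = obs, permuted = perm, nPerm = nPerm)
}
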