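#' Variant presence/absence per pool
#'
#' A variant counts as detected in a pool when at least `minAltReads` reads
#' support the alternate allele (default 2, so a single possibly erroneous
#' read does not register a detection).
#'
#' @param pc A [PoolCounts].
#' @param minAltReads Minimum alternate reads for presence.
#' @return Logical matrix, sites x pools.
#' @export
presenceMatrix <- function(pc, minAltReads = 2) {
    a <- SummarizedExperiment::assay(pc, "altReads")
    out <- a >= minAltReads
    dimnames(out) <- list(NULL, colnames(pc))
    out
}

#' Shared-variation counts between pools
#'
#' Off-diagonal entries count sites at which the variant is detected in
#' both pools; the diagonal holds each pool's own variant count, so every
#' off-diagonal entry is bounded by the smaller of the two diagonals.
#'
#' @param presence Logical sites x pools matrix from [presenceMatrix()].
#' @return Symmetric integer pools x pools matrix.
#' @export
sharedVariantCounts <- function(presence) {
    m <- crossprod(presence * 1L)
    storage.mode(m) <- "integer"
    m
}

#' Pairwise relationship coefficients from shared-variation counts
#'
#' Dice: `r_ij = 2 N_ij / (N_ii + N_jj)`; cosine (Ochiai):
#' `r_ij = N_ij / sqrt(N_ii N_jj)`. Both are identity-by-state style
#' similarities in \[0, 1\] with unit diagonal. A pool with no variants at
#' all has undefined coefficients (`NA`, with a warning).
#'
#' @param svm Matrix from [sharedVariantCounts()].
#' @param method `"dice"` (default) or `"cosine"`. For the KING-robust
#'   pseudo-genotype route, see [kingMatrix()].
#' @return Symmetric numeric matrix with attribute `method`.
#' @examples
#' svm <- matrix(c(100, 50, 50, 100), 2)
#' relationshipCoefficients(svm)[1, 2]  # 0.5
#' @export
relationshipCoefficients <- function(svm, method = c("dice", "cosine")) {
    method <- match.arg(method)
    n <- diag(svm)
    if (any(n == 0))
        warning("pool(s) with zero variants: ",
                paste(colnames(svm)[n == 0], collapse = ", "),
                "; coefficients set NA")
    r <- switch(method,
        dice = 2 * svm / outer(n, n, `+`),
        cosine = svm / sqrt(outer(n, n)))
    r[!is.finite(r)] <- NA_real_
    r[n == 0, ] <- NA_real_
    r[, n == 0] <- NA_real_
    diag(r)[n > 0] <- 1
    attr(r, "method") <- method
    r
}

#' Pseudo-genotypes from pool frequencies
#'
#' Pools are not diploid individuals; to feed diploid-genotype estimators
#' each pool frequency is discretized to a genotype-like code: 0
#' (reference-like, q < tLow), 1 (heterozygous-like), 2 (alternate-like,
#' q > tHigh). Missing frequencies propagate as `NA`.
#'
#' @param fm Frequency matrix from [alleleFrequency()].
#' @param tLow,tHigh Thresholds with `0 <= tLow < tHigh <= 1`
#'   (defaults 0.25, 0.75).
#' @return Integer matrix of codes 0/1/2 with `NA` for missing.
#' @export
pseudoGenotypes <- function(fm, tLow = 0.25, tHigh = 0.75) {
    if (!(tLow >= 0 && tLow < tHigh && tHigh <= 1))
        stop("need 0 <= tLow < tHigh <= 1")
    g <- matrix(1L, nrow(fm), ncol(fm), dimnames = dimnames(fm))
    g[!is.na(fm) & fm < tLow] <- 0L
    g[!is.na(fm) & fm > tHigh] <- 2L
    g[is.na(fm)] <- NA_integer_
    g
}

#' KING-robust kinship between two genotype vectors
#'
#' The robust within-family estimator
#' `phi = (N_het,het - 2 N_opposite_hom) / (N_het(i) + N_het(j))`
#' over sites non-missing in both samples, where `N_het,het` counts sites
#' heterozygous in both, `N_opposite_hom` sites homozygous for opposite
#' alleles, and `N_het(.)` the per-sample heterozygous-site counts among the
#' shared sites. Identical vectors with at least one heterozygous site give
#' 0.5 (self-kinship); unrelated or opposing samples can go negative.
#'
#' @param gi,gj Integer genotype vectors coded 0/1/2 (`NA` = missing).
#' @return Kinship estimate, or `NA` with a warning when no heterozygous
#'   sites exist in either sample.
#' @examples
#' g <- c(0L, 1L, 2L, 1L)
#' kingRobust(g, g)  # 0.5
#' @export
kingRobust <- function(gi, gj) {
    keep <- !is.na(gi) & !is.na(gj)
    gi <- gi[keep]; gj <- gj[keep]
    hetHet <- sum(gi == 1L & gj == 1L)
    oppHom <- sum((gi == 0L & gj == 2L) | (gi == 2L & gj == 0L))
    hetI <- sum(gi == 1L); hetJ <- sum(gj == 1L)
    if (hetI + hetJ == 0L) {
        warning("no heterozygous sites; kinship undefined")
        return(NA_real_)
    }
    (hetHet - 2 * oppHom) / (hetI + hetJ)
}

#' Pairwise KING-robust kinship matrix
#'
#' @param genotypes Integer sites x pools matrix from [pseudoGenotypes()].
#' @return Symmetric matrix of pairwise kinship estimates, diagonal 0.5,
#'   attribute `method = "king_pseudo"`.
#' @export
kingMatrix <- function(genotypes) {
    k <- ncol(genotypes)
    pools <- colnames(genotypes)
    m <- matrix(NA_real_, k, k, dimnames = list(pools, pools))
    for (i in seq_len(k)) {
        m[i, i] <- 0.5
        for (j in seq_len(k)[-seq_len(i)]) {
            m[i, j] <- m[j, i] <-
                suppressWarnings(kingRobust(genotypes[, i], genotypes[, j]))
        }
    }
    attr(m, "method") <- "king_pseudo"
    m
}

## Coefficient matrix -> distance matrix. Dice/cosine live in [0,1] so
## d = 1 - r >= 0; KING-robust can be negative, so d = max(0.5 - phi, 0)
## anchors self-kinship 0.5 at distance 0.
coefficientDistance <- function(rm, method = attr(rm, "method")) {
    if (is.null(method)) method <- "dice"
    if (anyNA(rm)) stop("relationship matrix has undefined entries")
    d <- if (method == "king_pseudo") pmax(0.5 - rm, 0) else 1 - rm
    diag(d) <- 0
    d
}

#' Neighbor-joining tree from a relationship matrix
#'
#' Converts coefficients to distances (`1 - r` for Dice/cosine;
#' `max(0.5 - phi, 0)` for KING-robust kinship) and applies Saitou-Nei
#' neighbor joining, which reconstructs additive distance matrices exactly.
#'
#' @param rm Relationship matrix from [relationshipCoefficients()] or
#'   [kingMatrix()], or a distance matrix when `isDistance = TRUE`.
#' @param isDistance Treat `rm` directly as distances.
#' @return An unrooted `ape::phylo` tree.
#' @export
njTree <- function(rm, isDistance = FALSE) {
    d <- if (isDistance) as.matrix(rm) else coefficientDistance(rm)
    if (anyNA(d)) stop("distance matrix has undefined entries")
    ape::nj(stats::as.dist(d))
}

#' Site-bootstrap support for the neighbor-joining tree
#'
#' Resamples sites (loci) with replacement `nReps` times, rebuilds the
#' relationship matrix and NJ tree from each replicate, and reports for each
#' internal edge of the original tree the fraction of replicate trees
#' containing the same bipartition of pools. Deterministic given `seed`.
#'
#' @param presence Logical sites x pools matrix from [presenceMatrix()]
#'   (for `method` `"dice"`/`"cosine"`), or a frequency matrix (for
#'   `"king_pseudo"`, discretized internally with default thresholds).
#' @param method Coefficient used for every tree.
#' @param nReps Bootstrap replicates (default 100).
#' @param seed Integer seed.
#' @return The original NJ tree (`phylo`) with `node.label` holding support
#'   fractions in \[0, 1\] (root node label empty).
#' @export
bootstrapSupport <- function(presence,
                             method = c("dice", "cosine", "king_pseudo"),
                             nReps = 100, seed = 1L) {
    method <- match.arg(method)
    if (nReps < 1) stop("nReps must be >= 1")
    buildTree <- function(x) {
        rm <- if (method == "king_pseudo") kingMatrix(pseudoGenotypes(x))
              else relationshipCoefficients(sharedVariantCounts(x), method)
        njTree(rm)
    }
    main <- buildTree(presence)
    set.seed(seed)
    nSites <- nrow(presence)
    reps <- lapply(seq_len(nReps), function(b) {
        idx <- sample.int(nSites, nSites, replace = TRUE)
        buildTree(presence[idx, , drop = FALSE])
    })
    counts <- ape::prop.clades(main, reps, rooted = FALSE)
    counts[is.na(counts)] <- 0L
    main$node.label <- counts / nReps
    main
}

#' Export the combined relationship table
#'
#' One square table in the conventional published layout: relationship
#' coefficients above the diagonal, shared-variant counts below, and each
#' pool's variant count on the diagonal.
#'
#' @param svm Shared-variation counts from [sharedVariantCounts()].
#' @param rm Relationship coefficients from [relationshipCoefficients()].
#' @param path Optional TSV output path.
#' @return The combined matrix (invisibly written to `path` if given).
#' @export
relationshipTable <- function(svm, rm, path = NULL) {
    out <- matrix(NA_real_, nrow(svm), ncol(svm), dimnames = dimnames(svm))
    out[lower.tri(out)] <- svm[lower.tri(svm)]
    out[upper.tri(out)] <- round(rm[upper.tri(rm)], 4)
    diag(out) <- diag(svm)
    if (!is.null(path))
        write.table(data.frame(pool = rownames(out), out,
                               check.names = FALSE),
                    path, sep = "\t", quote = FALSE, row.names = FALSE)
    out
}
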