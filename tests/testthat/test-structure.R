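test_that("PCA satisfies the factorization identities", {
    set.seed(71)
    fm <- matrix(runif(8 * 200), 200, 8,
                 dimnames = list(NULL, paste0("p", 1:8)))
    p <- poolPca(fm)
    # reconstruction: scores %*% t(loadings) gives back the centered matrix
    x <- t(fm); x <- scale(x, center = TRUE, scale = FALSE)
    recon <- p$scores %*% t(p$loadings)
    expect_lt(max(abs(recon - x)), 1e-8)
    expect_true(all(p$varianceExplained >= 0 & p$varianceExplained <= 1))
    expect_lt(abs(sum(p$varianceExplained) - 1), 1e-9)
    # centered data: component scores have zero mean
    expect_lt(max(abs(colMeans(p$scores))), 1e-10)
})

test_that("rank-1 two-centroid data put all variance on PC1", {
    c1 <- runif(50); c2 <- c1 + 0.3
    fm <- cbind(a1 = c1, a2 = c1, b1 = c2, b2 = c2)
    p <- poolPca(fm)
    expect_equal(p$varianceExplained[1], 1, tolerance = 1e-12)
    expect_gt(abs(mean(p$scores[c("a1", "a2"), 1]) -
                  mean(p$scores[c("b1", "b2"), 1])), 0)
})

test_that("PCA variance is order-invariant and errors on degenerate input", {
    set.seed(73)
    fm <- matrix(runif(5 * 60), 60, 5, dimnames = list(NULL, letters[1:5]))
    p1 <- poolPca(fm)
    p2 <- poolPca(fm[, c(3, 1, 5, 2, 4)])
    expect_equal(p1$varianceExplained, p2$varianceExplained)
    expect_error(poolPca(fm[1, , drop = FALSE]), "at least 2")
    # missing sites are dropped, count logged
    fm[3, 2] <- NA
    expect_equal(poolPca(fm)$nSitesUsed, 59)
    # chromosome scoping restricts the site set (the NA site is on chr1)
    chrom <- rep(c("chr1", "chr2"), each = 30)
    expect_equal(poolPca(fm, chrom = chrom, scope = "chr1")$nSitesUsed, 29)
    expect_equal(poolPca(fm, chrom = chrom, scope = "chr2")$nSitesUsed, 30)
})

test_that("AMOVA equals the sums-of-squares oracle on hand-built data", {
    h <- fourPoolHierarchy()
    fm <- matrix(c(0.1, 0.2, 0.8, 0.9,
                   0.0, 0.1, 0.9, 1.0,
                   0.5, 0.4, 0.6, 0.5), 3, 4, byrow = TRUE,
                 dimnames = list(NULL, c("A", "B", "C", "D")))
    res <- poolAmova(fm, h)
    # oracle: explicit group means and scalar sums of squares
    x <- t(fm)
    grand <- colMeans(x)
    m1 <- colMeans(x[1:2, ]); m2 <- colMeans(x[3:4, ])
    ssCt <- 2 * sum((m1 - grand)^2) + 2 * sum((m2 - grand)^2)
    ssAcc <- sum((x[1, ] - m1)^2) + sum((x[2, ] - m1)^2) +
             sum((x[3, ] - m2)^2) + sum((x[4, ] - m2)^2)
    expect_equal(res$table$SS[1], ssCt, tolerance = 1e-10)
    expect_equal(res$table$SS[2], ssAcc, tolerance = 1e-10)
    expect_equal(res$table$SS[3], 0)
    # balanced one-pool-per-accession design: n1 = 1, n2 = 1, n3 = 2
    msCt <- ssCt / 1; msAcc <- ssAcc / 2
    sigAcc <- msAcc; sigCt <- (msCt - msAcc) / 2
    expect_equal(res$table$sigma[2], sigAcc, tolerance = 1e-10)
    expect_equal(res$table$sigma[1], max(sigCt, 0), tolerance = 1e-10)
    expect_match(paste(res$flags, collapse = " "), "0 df")
})

test_that("AMOVA matches the oracle on random multi-pool-accession fixtures", {
    set.seed(79)
    tb <- data.frame(pool_id = paste0("p", 1:6),
                     accession = c("a1", "a1", "a2", "b1", "b1", "b2"),
                     crop_type = c("A", "A", "A", "B", "B", "B"),
                     species = "sp")
    h <- LineageHierarchy(tb)
    for (rep in 1:10) {
        fm <- matrix(runif(6 * 20), 20, 6,
                     dimnames = list(NULL, tb$pool_id))
        res <- poolAmova(fm, h)
        x <- t(fm); N <- 6
        accOf <- tb$accession; ctOf <- tb$crop_type
        grand <- colMeans(x)
        ssT <- sum(sweep(x, 2, grand)^2)
        ssW <- ssA <- ssC <- 0
        for (ac in unique(accOf)) {
            xa <- x[accOf == ac, , drop = FALSE]
            ma <- colMeans(xa)
            ssW <- ssW + sum(sweep(xa, 2, ma)^2)
            ct <- unique(ctOf[accOf == ac])
            mc <- colMeans(x[ctOf == ct, , drop = FALSE])
            ssA <- ssA + nrow(xa) * sum((ma - mc)^2)
        }
        for (ct in unique(ctOf)) {
            xc <- x[ctOf == ct, , drop = FALSE]
            ssC <- ssC + nrow(xc) * sum((colMeans(xc) - grand)^2)
        }
        expect_equal(sum(res$table$SS), ssT, tolerance = 1e-10)
        expect_equal(res$table$SS, c(ssC, ssA, ssW), tolerance = 1e-10)
        # variance components from the weighted-n normal equations
        dfC <- 1; dfA <- 2; dfW <- 2   # N - a = 6 - 4
        sqByCt <- (2^2 + 1^2) / 3 + (2^2 + 1^2) / 3
        n1 <- (N - sqByCt) / dfA
        n2 <- (sqByCt - (2^2 + 1^2 + 2^2 + 1^2) / N) / dfC
        n3 <- (N - (3^2 + 3^2) / N) / dfC
        sW <- ssW / dfW
        sA <- (ssA / dfA - sW) / n1
        sC <- (ssC / dfC - sW - n2 * sA) / n3
        expect_equal(res$table$sigma, pmax(c(sC, sA, sW), 0),
                     tolerance = 1e-10)
        expect_equal(sum(res$table$percent), 100, tolerance = 1e-6)
    }
})

test_that("identical pools give zero components throughout", {
    h <- fourPoolHierarchy()
    fm <- matrix(0.4, 5, 4, dimnames = list(NULL, c("A", "B", "C", "D")))
    res <- poolAmova(fm, h)
    expect_equal(res$table$sigma, c(0, 0, 0))
})

test_that("among-crop-type percent grows with the crop-type drift", {
    pctAt <- function(fct, s) {
        tr <- simulateFrequencies(simParams(nCropTypes = 3,
            accessionsPerType = 3, nLoci = 1000, fCropType = fct,
            fAccession = 0.01, seed = s))
        pc <- samplePoolCounts(tr, seed = s + 500)
        fm <- alleleFrequency(filterSites(pc, 15, TRUE, c("SNP", "indel")))
        poolAmova(fm, tr@hierarchy)$table$percent[1]
    }
    wins <- sum(vapply(1:10, function(s) pctAt(0.2, s) > pctAt(0.01, s),
                       logical(1)))
    expect_gte(wins, 9)
})

test_that("AMOVA permutation p-values behave at both extremes", {
    # strong structure: minimal attainable p = 1/(nPerm+1)
    tr <- simulateFrequencies(simParams(nCropTypes = 2,
        accessionsPerType = 3, nLoci = 600, fCropType = 0.3,
        fAccession = 0.01, seed = 83))
    fm <- t(tr@accessionFreqs)
    perm <- amovaPermutation(fm, tr@hierarchy, nPerm = 19, seed = 3)
    # no permuted grouping can beat perfect separation: p is bounded below
    # by 1/(nPerm+1) and only label reshuffles equal to the observed
    # grouping (exact ties) can lift it above the bound
    expect_gte(perm$p.value, 1 / 20)
    expect_equal(perm$p.value,
                 (1 + sum(perm$permuted == perm$observed)) / 20)
    expect_true(all(perm$permuted <= perm$observed))
    # reproducible given the seed
    perm2 <- amovaPermutation(fm, tr@hierarchy, nPerm = 19, seed = 3)
    expect_identical(perm$p.value, perm2$p.value)
    # no group structure: p should usually be non-significant
    ps <- vapply(1:10, function(s) {
        tr0 <- simulateFrequencies(simParams(nCropTypes = 2,
            accessionsPerType = 3, nLoci = 300, fCropType = 0,
            fAccession = 0.05, seed = 900 + s))
        amovaPermutation(t(tr0@accessionFreqs), tr0@hierarchy,
                         nPerm = 39, seed = s)$p.value
    }, numeric(1))
    expect_gte(sum(ps > 0.05), 7)
})

test_that("PCA separates crop types when drift is strongly nested", {
    skip_if_not_installed("cluster")
    ok <- vapply(1:10, function(s) {
        tr <- simulateFrequencies(simParams(nCropTypes = 3,
            accessionsPerType = 4, nLoci = 800, fCropType = 0.25,
            fAccession = 0.01, seed = 300 + s))
        pc <- samplePoolCounts(tr, seed = 400 + s)
        fm <- alleleFrequency(filterSites(pc, 15, TRUE, c("SNP", "indel")))
        p <- poolPca(fm)
        ct <- as.integer(factor(hierarchyTable(tr@hierarchy)$crop_type))
        sil <- cluster::silhouette(ct, dist(p$scores[, 1:2]))
        mean(sil[, "sil_width"]) > 0
    }, logical(1))
    expect_gte(sum(ok), 10 * 0.95 - 1e-9)
})
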