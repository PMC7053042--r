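test_that("presenceMatrix thresholds alternate reads", {
    depth <- matrix(20, 3, 2); alt <- matrix(c(0, 1, 2, 5, 0, 1), 3, 2)
    pc <- toyPoolCounts(depth, alt)
    p2 <- presenceMatrix(pc, 2)
    expect_equal(as.vector(p2), c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE))
    p1 <- presenceMatrix(pc, 1)
    # thresholds 1 vs 2 differ exactly at singleton-alt cells
    expect_equal(which(p1 != p2), which(alt == 1))
    expect_false(any(presenceMatrix(toyPoolCounts(depth, matrix(0L, 3, 2)))))
})

test_that("shared counts match a double-loop oracle and its invariants", {
    set.seed(47)
    pres <- matrix(runif(100) < 0.4, 20, 5,
                   dimnames = list(NULL, paste0("p", 1:5)))
    svm <- sharedVariantCounts(pres)
    oracle <- matrix(0L, 5, 5)
    for (i in 1:5) for (j in 1:5)
        oracle[i, j] <- sum(pres[, i] & pres[, j])
    expect_equal(unname(svm), oracle)
    expect_true(isSymmetric(svm))
    for (i in 1:4) for (j in (i + 1):5)
        expect_lte(svm[i, j], min(svm[i, i], svm[j, j]))
    # identical and disjoint columns
    pres2 <- cbind(a = c(TRUE, TRUE, FALSE), b = c(TRUE, TRUE, FALSE),
                   c = c(FALSE, FALSE, TRUE))
    s2 <- sharedVariantCounts(pres2)
    expect_equal(s2["a", "b"], s2["a", "a"])
    expect_equal(s2["a", "c"], 0L)
})

test_that("dice and cosine coefficients are bounded with unit diagonal", {
    svm <- matrix(c(100, 50, 50, 100), 2,
                  dimnames = list(c("a", "b"), c("a", "b")))
    expect_equal(relationshipCoefficients(svm, "dice")["a", "b"], 0.5)
    expect_equal(relationshipCoefficients(svm, "cosine")["a", "b"], 0.5)
    set.seed(53)
    for (rep in 1:20) {
        pres <- matrix(runif(80) < runif(1, 0.2, 0.8), 20, 4)
        colnames(pres) <- paste0("p", 1:4)
        svm <- sharedVariantCounts(pres)
        if (any(diag(svm) == 0)) next
        for (m in c("dice", "cosine")) {
            r <- relationshipCoefficients(svm, m)
            expect_true(all(r >= 0 & r <= 1))
            expect_equal(unname(diag(r)), rep(1, 4))
            expect_true(isSymmetric(unname(r)))
        }
    }
    svm0 <- matrix(c(0L, 0L, 0L, 10L), 2,
                   dimnames = list(c("a", "b"), c("a", "b")))
    expect_warning(r0 <- relationshipCoefficients(svm0), "zero")
    expect_true(is.na(r0["a", "b"]))
})

test_that("pseudo-genotype discretization matches its oracle", {
    expect_error(pseudoGenotypes(matrix(0.5), 0.5, 0.5), "tLow")
    fm <- matrix(c(0.1, 0.5, 0.9, NA), 1)
    expect_equal(as.vector(pseudoGenotypes(fm)), c(0L, 1L, 2L, NA))
    set.seed(59)
    m <- matrix(runif(200), 40, 5)
    g <- pseudoGenotypes(m, 0.3, 0.6)
    for (i in seq_along(m)) {
        want <- if (m[i] < 0.3) 0L else if (m[i] > 0.6) 2L else 1L
        expect_identical(g[i], want)
    }
})

test_that("kingRobust reproduces the category-count formula", {
    g <- c(0L, 1L, 2L, 1L, 0L)
    expect_equal(kingRobust(g, g), 0.5)  # self-kinship limit
    # all opposite homozygotes with h hets each: phi = -2 N_opp / (2 h)
    gi <- c(0L, 0L, 2L, 1L); gj <- c(2L, 2L, 0L, 1L)
    expect_equal(kingRobust(gi, gj), (1 - 2 * 3) / (1 + 1))
    expect_warning(kingRobust(c(0L, 2L), c(0L, 2L)), "heterozygous")
    # random vectors vs a brute-force tally
    set.seed(61)
    for (rep in 1:25) {
        gi <- sample(c(0:2, NA), 60, TRUE)
        gj <- sample(c(0:2, NA), 60, TRUE)
        both <- !is.na(gi) & !is.na(gj)
        hh <- opp <- hi <- hj <- 0
        for (k in which(both)) {
            if (gi[k] == 1 && gj[k] == 1) hh <- hh + 1
            if (abs(gi[k] - gj[k]) == 2) opp <- opp + 1
            if (gi[k] == 1) hi <- hi + 1
            if (gj[k] == 1) hj <- hj + 1
        }
        if (hi + hj == 0) next
        expect_equal(kingRobust(gi, gj), (hh - 2 * opp) / (hi + hj))
    }
})

test_that("NJ recovers additive four-taxon trees exactly", {
    # tree ((A:2,B:3):1,(C:4,D:5)) -> additive distances by path length
    d <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
    d["A", "B"] <- d["B", "A"] <- 2 + 3
    d["A", "C"] <- d["C", "A"] <- 2 + 1 + 4
    d["A", "D"] <- d["D", "A"] <- 2 + 1 + 5
    d["B", "C"] <- d["C", "B"] <- 3 + 1 + 4
    d["B", "D"] <- d["D", "B"] <- 3 + 1 + 5
    d["C", "D"] <- d["D", "C"] <- 4 + 5
    tree <- njTree(d, isDistance = TRUE)
    expect_lt(max(abs(as.matrix(ape::cophenetic.phylo(tree))[
        rownames(d), colnames(d)] - d)), 1e-9)
    # AB form a cherry
    pp <- ape::prop.part(tree)
    sets <- lapply(pp, function(i) sort(attr(pp, "labels")[i]))
    expect_true(any(vapply(sets, identical, logical(1), c("A", "B"))) ||
                any(vapply(sets, identical, logical(1), c("C", "D"))))
})

test_that("three taxa resolve by the closed-form three-point formulas", {
    d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
                dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
    tree <- njTree(d, isDistance = TRUE)
    el <- setNames(tree$edge.length,
                   tree$tip.label[tree$edge[, 2]])
    expect_equal(el[["x"]], (3 + 4 - 5) / 2)
    expect_equal(el[["y"]], (3 + 5 - 4) / 2)
    expect_equal(el[["z"]], (4 + 5 - 3) / 2)
})

test_that("ultrametric two-cluster matrices make clusters sister", {
    d <- matrix(1, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
    diag(d) <- 0
    d["A", "B"] <- d["B", "A"] <- 0.2
    d["C", "D"] <- d["D", "C"] <- 0.2
    tree <- njTree(d, isDistance = TRUE)
    pp <- ape::prop.part(tree)
    sets <- lapply(pp, function(i) sort(attr(pp, "labels")[i]))
    expect_true(any(vapply(sets, identical, logical(1), c("A", "B"))) ||
                any(vapply(sets, identical, logical(1), c("C", "D"))))
})

test_that("bootstrap support is deterministic and bounded", {
    set.seed(67)
    pres <- matrix(runif(200) < 0.5, 40, 5,
                   dimnames = list(NULL, paste0("p", 1:5)))
    t1 <- bootstrapSupport(pres, "dice", nReps = 25, seed = 7)
    t2 <- bootstrapSupport(pres, "dice", nReps = 25, seed = 7)
    expect_identical(t1$node.label, t2$node.label)
    expect_true(all(t1$node.label >= 0 & t1$node.label <= 1))
    tOne <- bootstrapSupport(pres, "dice", nReps = 1, seed = 8)
    expect_true(all(tOne$node.label %in% c(0, 1)))
    expect_error(bootstrapSupport(pres, "dice", nReps = 0), "nReps")
})

test_that("within-crop-type similarity exceeds between when drift is nested", {
    for (s in 1:5) {
        tr <- simulateFrequencies(simParams(nCropTypes = 2,
            accessionsPerType = 3, nLoci = 1500, fCropType = 0.2,
            fAccession = 0.01, seed = 100 + s))
        pc <- samplePoolCounts(tr, seed = 200 + s)
        svm <- sharedVariantCounts(presenceMatrix(filterSites(
            pc, 15, TRUE, c("SNP", "indel"))))
        r <- relationshipCoefficients(svm)
        ct <- hierarchyTable(tr@hierarchy)$crop_type
        same <- outer(ct, ct, "==") & upper.tri(r)
        diff <- outer(ct, ct, "!=") & upper.tri(r)
        expect_gt(mean(r[same]), mean(r[diff]))
    }
})
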