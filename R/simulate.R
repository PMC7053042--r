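#' Simulation parameters for hierarchical pool-seq data
#'
#' Builds and validates the parameter set of the Balding-Nichols style
#' generator. Defaults reproduce the sequencing design the package targets:
#' four crop types holding 10/7/2/4 accessions (23 pools), 25 individuals
#' per pool, ~80X pooled depth over 9 chromosomes.
#'
#' @param nCropTypes Number of crop-type lineages.
#' @param accessionsPerType Accessions per crop type; a single count or a
#'   vector of length `nCropTypes`.
#' @param nIndividuals Diploid individuals pooled per accession (25).
#' @param nLoci Number of independent variant loci to simulate.
#' @param ancestralShape Length-2 shape of the Beta law for ancestral
#'   frequencies; the default `c(0.8, 0.8)` is U-shaped, mimicking a site
#'   frequency spectrum enriched for rare alleles.
#' @param fCropType Drift (FST-like) parameter in \[0, 1) for crop-type
#'   divergence from the ancestral pool; 0 means no drift.
#' @param fAccession Drift parameter in \[0, 1) for accession divergence
#'   within a crop type.
#' @param meanDepth Expected reads per site per pool (Poisson mean, ~80).
#' @param errorRate Per-read symmetric miscall probability.
#' @param nChromosomes Chromosomes loci are assigned to uniformly (9).
#' @param indelFraction Fraction of loci labelled indel rather than SNP.
#' @param seed Integer seed stored with the parameters.
#' @return A validated named list of class `"SimParams"`.
#' @examples
#' p <- simParams(nLoci = 500, seed = 1)
#' p$meanDepth
#' @export
simParams <- function(nCropTypes = 4,
                      accessionsPerType = c(10, 7, 2, 4),
                      nIndividuals = 25,
                      nLoci = 10000,
                      ancestralShape = c(0.8, 0.8),
                      fCropType = 0.1,
                      fAccession = 0.02,
                      meanDepth = 80,
                      errorRate = 0.001,
                      nChromosomes = 9,
                      indelFraction = 0.1,
                      seed = 1L) {
    if (length(accessionsPerType) == 1L)
        accessionsPerType <- rep(accessionsPerType, nCropTypes)
    if (length(accessionsPerType) != nCropTypes)
        stop("accessionsPerType must have length 1 or nCropTypes")
    counts <- c(nCropTypes, accessionsPerType, nIndividuals, nLoci,
                nChromosomes)
    if (any(counts < 1) || any(counts != round(counts)))
        stop("all counts must be integers >= 1")
    for (nm in c("fCropType", "fAccession", "errorRate", "indelFraction")) {
        v <- get(nm)
        if (v < 0 || v >= 1) stop(nm, " must lie in [0, 1)")
    }
    if (meanDepth <= 0) stop("meanDepth must be positive")
    if (length(ancestralShape) != 2L || any(ancestralShape <= 0))
        stop("ancestralShape must be two positive shape parameters")
    structure(list(
        nCropTypes = as.integer(nCropTypes),
        accessionsPerType = as.integer(accessionsPerType),
        nIndividuals = as.integer(nIndividuals),
        nLoci = as.integer(nLoci),
        ancestralShape = as.numeric(ancestralShape),
        fCropType = fCropType, fAccession = fAccession,
        meanDepth = meanDepth, errorRate = errorRate,
        nChromosomes = as.integer(nChromosomes),
        indelFraction = indelFraction,
        seed = as.integer(seed)), class = "SimParams")
}

## Balding-Nichols draw: child ~ Beta(p(1-F)/F, (1-p)(1-F)/F).
## F = 0 is the no-drift limit (child = parent); parental frequencies of
## exactly 0 or 1 are absorbing (a lost/fixed allele cannot re-segregate).
.bnDraw <- function(parent, f) {
    if (f == 0) return(parent)
    out <- parent
    seg <- parent > 0 & parent < 1
    if (any(seg)) {
        k <- (1 - f) / f
        out[seg] <- rbeta(sum(seg), parent[seg] * k, (1 - parent[seg]) * k)
    }
    out
}

.simLineageNames <- function(params) {
    ct <- paste0("CT", seq_len(params$nCropTypes))
    acc <- unlist(lapply(seq_len(params$nCropTypes), function(i)
        paste0(ct[i], "_A", seq_len(params$accessionsPerType[i]))))
    list(cropTypes = ct, accessions = acc,
         accCropType = rep(ct, params$accessionsPerType))
}

#' Simulate hierarchical allele frequencies
#'
#' Draws latent allele frequencies under a two-level Balding-Nichols model:
#' ancestral frequencies from `Beta(ancestralShape)`, crop-type frequencies
#' drifted from the ancestral pool with parameter `fCropType`, and accession
#' frequencies drifted from their crop type with `fAccession`. Loci are
#' assigned uniformly to chromosomes. Deterministic given the seed.
#'
#' @param params A `SimParams` list from [simParams()].
#' @param seed Optional seed overriding `params$seed`.
#' @return A [PoolSimTruth] with frequencies at every level, locus
#'   coordinates and the matching [LineageHierarchy].
#' @examples
#' tr <- simulateFrequencies(simParams(nLoci = 200, seed = 7))
#' dim(tr@accessionFreqs)
#' @export
simulateFrequencies <- function(params, seed = params$seed) {
    stopifnot(inherits(params, "SimParams"))
    set.seed(seed)
    L <- params$nLoci
    anc <- rbeta(L, params$ancestralShape[1], params$ancestralShape[2])
    nm <- .simLineageNames(params)
    ctF <- t(vapply(seq_along(nm$cropTypes), function(i)
        .bnDraw(anc, params$fCropType), numeric(L)))
    rownames(ctF) <- nm$cropTypes
    accF <- t(vapply(seq_along(nm$accessions), function(i)
        .bnDraw(ctF[nm$accCropType[i], ], params$fAccession), numeric(L)))
    rownames(accF) <- nm$accessions
    chromIdx <- sample.int(params$nChromosomes, L, replace = TRUE)
    chrom <- paste0("chr", chromIdx)
    pos <- integer(L)
    for (k in seq_len(params$nChromosomes)) {
        idx <- which(chromIdx == k)
        pos[idx] <- seq_along(idx) * 100L
    }
    hier <- LineageHierarchy(data.frame(
        pool_id = nm$accessions, accession = nm$accessions,
        crop_type = nm$accCropType, species = "simulated",
        stringsAsFactors = FALSE))
    new("PoolSimTruth", ancestralFreqs = anc, cropTypeFreqs = ctF,
        accessionFreqs = accF,
        injectedLSV = data.frame(locus = integer(), lineage = character(),
                                 level = character()),
        chrom = chrom, pos = pos, params = unclass(params), hierarchy = hier)
}

#' Inject lineage-private fixed variants into a simulation truth
#'
#' Appends `nVariants` loci that are fixed (frequency 1) in every accession
#' inside the named lineage and absent (frequency 0) in every accession
#' outside it — the ground truth against which the lineage-specific
#' variation scan is validated.
#'
#' @param truth A [PoolSimTruth].
#' @param lineage Accession or crop-type label (must exist in the truth's
#'   hierarchy at `level`).
#' @param level `"accession"` or `"crop_type"`.
#' @param nVariants Number of private loci to append.
#' @param seed Seed for chromosome assignment of the new loci.
#' @return The augmented [PoolSimTruth]; `injectedLSV(truth)` records the
#'   appended loci.
#' @examples
#' tr <- simulateFrequencies(simParams(nLoci = 100, seed = 1))
#' tr2 <- injectLSV(tr, accessions(tr@hierarchy)[1], "accession", 10)
#' nrow(injectedLSV(tr2))
#' @export
injectLSV <- function(truth, lineage, level = c("accession", "crop_type"),
                      nVariants, seed = 1L) {
    level <- match.arg(level)
    tb <- hierarchyTable(truth@hierarchy)
    valid <- if (level == "accession") unique(tb$accession) else
        unique(tb$crop_type)
    if (!lineage %in% valid)
        stop("unknown ", level, " '", lineage, "'; valid: ",
             paste(valid, collapse = ", "))
    memberAcc <- unique(tb$accession[
        if (level == "accession") tb$accession == lineage
        else tb$crop_type == lineage])
    L0 <- length(truth@ancestralFreqs)
    n <- as.integer(nVariants)
    set.seed(seed)
    accNew <- matrix(0, nrow(truth@accessionFreqs), n,
                     dimnames = list(rownames(truth@accessionFreqs), NULL))
    accNew[memberAcc, ] <- 1
    ctNew <- matrix(0, nrow(truth@cropTypeFreqs), n,
                    dimnames = list(rownames(truth@cropTypeFreqs), NULL))
    for (ct in rownames(ctNew)) {
        inCt <- tb$accession[tb$crop_type == ct]
        ctNew[ct, ] <- mean(accNew[inCt, 1])
    }
    chromIdx <- sample.int(truth@params$nChromosomes, n, replace = TRUE)
    newChrom <- paste0("chr", chromIdx)
    newPos <- integer(n)
    for (k in seq_len(truth@params$nChromosomes)) {
        prev <- sum(truth@chrom == paste0("chr", k))
        idx <- which(chromIdx == k)
        newPos[idx] <- (prev + seq_along(idx)) * 100L
    }
    rec <- data.frame(locus = L0 + seq_len(n), lineage = lineage,
                      level = level, stringsAsFactors = FALSE)
    new("PoolSimTruth",
        ancestralFreqs = c(truth@ancestralFreqs, rep(0, n)),
        cropTypeFreqs = cbind(truth@cropTypeFreqs, ctNew),
        accessionFreqs = cbind(truth@accessionFreqs, accNew),
        injectedLSV = rbind(truth@injectedLSV, rec),
        chrom = c(truth@chrom, newChrom),
        pos = c(truth@pos, newPos),
        params = truth@params, hierarchy = truth@hierarchy)
}

#' Sample pooled read counts from a simulation truth
#'
#' Per accession and locus: the pooled allele count is drawn
#' `Binomial(2 * nIndividuals, accession frequency)` giving the realized
#' pool frequency g; read depth is `Poisson(meanDepth)`; alternate reads are
#' `Binomial(depth, g (1 - e) + (1 - g) e)` with symmetric per-read error e;
#' reference reads make up the remainder. Loci are labelled SNP or indel
#' according to `indelFraction` (injected loci included), with the biallelic
#' flag set.
#'
#' @param truth A [PoolSimTruth].
#' @param params `SimParams`; defaults to the truth's own parameters.
#' @param seed Seed for the sampling stage.
#' @return A [PoolCounts] whose `colData` carries the hierarchy columns.
#' @examples
#' tr <- simulateFrequencies(simParams(nLoci = 50, seed = 2))
#' pc <- samplePoolCounts(tr, seed = 2)
#' dim(pc)
#' @export
samplePoolCounts <- function(truth, params = NULL, seed = 1L) {
    if (is.null(params)) params <- truth@params
    params <- unclass(params)
    set.seed(seed)
    accF <- truth@accessionFreqs
    nAcc <- nrow(accF); L <- ncol(accF)
    twoN <- 2L * params$nIndividuals
    g <- matrix(rbinom(nAcc * L, twoN, accF) / twoN, nAcc, L)
    depth <- matrix(rpois(nAcc * L, params$meanDepth), nAcc, L)
    e <- params$errorRate
    pAlt <- g * (1 - e) + (1 - g) * e
    alt <- matrix(rbinom(nAcc * L, as.vector(depth), as.vector(pAlt)),
                  nAcc, L)
    isIndel <- sample(c(TRUE, FALSE), L, replace = TRUE,
                      prob = c(params$indelFraction, 1 - params$indelFraction))
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, L, replace = TRUE)
    altAllele <- vapply(seq_len(L), function(i) {
        if (isIndel[i]) paste0(ref[i], sample(bases, 1))
        else sample(setdiff(bases, ref[i]), 1)
    }, character(1))
    vt <- data.frame(chrom = truth@chrom, pos = truth@pos,
                     ref = ref, alt = altAllele,
                     variantClass = ifelse(isIndel, "indel", "SNP"),
                     biallelic = TRUE, stringsAsFactors = FALSE)
    ## rows stay in truth locus order so injectedLSV indices map directly
    pc <- PoolCounts(t(depth), t(depth - alt), t(alt), vt,
                     poolIds = rownames(accF))
    cd <- hierarchyTable(truth@hierarchy)
    stopifnot(identical(cd$pool_id, rownames(accF)))
    SummarizedExperiment::colData(pc)$accession <- cd$accession
    SummarizedExperiment::colData(pc)$crop_type <- cd$crop_type
    SummarizedExperiment::colData(pc)$species <- cd$species
    pc
}

#' Moment estimator of FST among groups from frequency vectors
#'
#' Ratio-of-sums variance-components estimator: with per-locus sample
#' variance s2 across the K group frequencies and mean pbar,
#' FST = sum(s2) / sum(pbar (1 - pbar) + s2 / K). Under the
#' Balding-Nichols model both numerator and denominator have expectation
#' proportional to pi(1 - pi), so the ratio recovers the drift parameter.
#'
#' @param freqs Matrix, groups x loci, of allele frequencies.
#' @return FST estimate (scalar).
#' @examples
#' tr <- simulateFrequencies(simParams(nLoci = 5000, fCropType = 0.1, seed = 3))
#' fstFromFrequencies(tr@cropTypeFreqs)
#' @export
fstFromFrequencies <- function(freqs) {
    K <- nrow(freqs)
    if (K < 2) stop("need at least two groups")
    pbar <- colMeans(freqs)
    s2 <- apply(freqs, 2, var)
    keep <- pbar > 0 & pbar < 1
    sum(s2[keep]) / sum(pbar[keep] * (1 - pbar[keep]) + s2[keep] / K)
}
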