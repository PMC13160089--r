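# Shared fixtures and independent oracles for the test suite.

# Quadratic-time brute-force FRiP: a read counts when it shares >= 1 bp
# with any peak (1-based closed coordinates, per chromosome).
bruteForceFrip <- function(reads, peaks) {
    rdf <- data.frame(chrom = as.character(GenomicRanges::seqnames(reads)),
                      start = GenomicRanges::start(reads),
                      end = GenomicRanges::end(reads))
    pdf <- data.frame(chrom = as.character(GenomicRanges::seqnames(peaks)),
                      start = GenomicRanges::start(peaks),
                      end = GenomicRanges::end(peaks))
    hits <- 0L
    for (i in seq_len(nrow(rdf))) {
        ov <- FALSE
        for (j in seq_len(nrow(pdf))) {
            if (rdf$chrom[i] == pdf$chrom[j] &&
                rdf$start[i] <= pdf$end[j] &&
                rdf$end[i] >= pdf$start[j]) { ov <- TRUE; break }
        }
        hits <- hits + ov
    }
    hits / nrow(rdf)
}

# Random interval fixture on a small genome.
randomIntervalFixture <- function(seed, maxReads = 100L, maxPeaks = 20L,
                                  chromLen = 10000L, nChroms = 2L) {
    set.seed(seed)
    nr <- sample.int(maxReads, 1L)
    np <- sample.int(maxPeaks, 1L)
    chroms <- paste0("chr", seq_len(nChroms))
    mk <- function(n, maxw) {
        s <- sample.int(chromLen - maxw, n, replace = TRUE)
        w <- sample.int(maxw, n, replace = TRUE)
        GenomicRanges::GRanges(sample(chroms, n, replace = TRUE),
                               IRanges::IRanges(start = s, width = w))
    }
    list(reads = mk(nr, 80L), peaks = mk(np, 400L))
}

# Exact stationary analysis of the single-extruder kernel on an n-site
# lattice with no barriers and no pausing. States: unloaded, plus every
# leg pair (l, r) with l < r (0-based). Mirrors the kernel's phase order:
# death, then same-step rebirth, then deterministic outward translocation.
# Returns the stationary expected leg-count distribution over sites,
# normalised to sum to 1 over recorded legs.
singleLefStationaryProfile <- function(nSites, pDeath, birthRate) {
    states <- list("U")
    for (l in 0:(nSites - 2)) for (r in (l + 1):(nSites - 1))
        states[[length(states) + 1L]] <- c(l, r)
    id <- function(s) {
        if (identical(s, "U")) return(1L)
        which(vapply(states[-1], function(x)
            x[1] == s[1] && x[2] == s[2], logical(1))) + 1L
    }
    nS <- length(states)
    P <- matrix(0, nS, nS)
    translocate <- function(l, r) c(max(l - 1, 0), min(r + 1, nSites - 1))
    # newborn at uniform adjacent pair (i, i+1), then translocated
    bornStates <- t(vapply(0:(nSites - 2), function(i)
        translocate(i, i + 1), numeric(2)))
    pPair <- 1 / (nSites - 1)
    addBirthRows <- function(row, w) {
        # with prob w*birthRate load and translocate; else stay unloaded
        P[row, 1] <<- P[row, 1] + w * (1 - birthRate)
        for (k in seq_len(nrow(bornStates)))
            P[row, id(bornStates[k, ])] <<-
                P[row, id(bornStates[k, ])] + w * birthRate * pPair
    }
    addBirthRows(1L, 1)
    for (s in 2:nS) {
        lr <- states[[s]]
        addBirthRows(s, pDeath)  # died this step, may reload same step
        to <- translocate(lr[1], lr[2])
        P[s, id(to)] <- P[s, id(to)] + (1 - pDeath)
    }
    stopifnot(max(abs(rowSums(P) - 1)) < 1e-12)
    pi <- rep(1 / nS, nS)
    for (it in 1:5000) {
        pi2 <- as.vector(pi %*% P)
        if (max(abs(pi2 - pi)) < 1e-14) { pi <- pi2; break }
        pi <- pi2
    }
    prof <- numeric(nSites)
    for (s in 2:nS) {
        lr <- states[[s]]
        prof[lr[1] + 1] <- prof[lr[1] + 1] + pi[s]
        prof[lr[2] + 1] <- prof[lr[2] + 1] + pi[s]
    }
    prof / sum(prof)
}

# Barrier set with explicit sites (bypasses sampling) for kernel tests.
manualBarrierSet <- function(positions, occupancies, sitesPerReplica,
                             orientation = "bidirectional",
                             anchorOccupancy = 0.65,
                             anchorBoundTime = 9.87 * 60) {
    uStar <- anchorBoundTime * (1 - anchorOccupancy) / anchorOccupancy
    boundT <- ifelse(occupancies >= 1, Inf,
                     uStar * occupancies / (1 - occupancies))
    new("BarrierSet",
        sites = S4Vectors::DataFrame(
            position = as.integer(positions),
            occupancy = as.numeric(occupancies),
            bound_time_s = boundT,
            unbound_time_s = rep(uStar, length(positions)),
            orientation = rep(orientation, length.out = length(positions))),
        sitesPerReplica = as.integer(sitesPerReplica),
        targetOccupancyPerMb = sum(occupancies),
        anchorOccupancy = anchorOccupancy,
        anchorBoundTime = anchorBoundTime)
}

emptyBarrierSet <- function(sitesPerReplica) {
    manualBarrierSet(integer(0), numeric(0), sitesPerReplica)
}
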