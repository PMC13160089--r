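#' @include AllClasses.R utils.R frip-intervals.R barrier-kinetics.R
NULL

#' ReadGenSpec: parameters of the synthetic read generator
#'
#' The generator is the generative twin of the uniform-background mixture:
#' each read is background with probability `backgroundFraction` (start
#' uniform over the genome) or signal otherwise (inside a random peak with
#' probability `inPeakProbSignal`, else uniform outside peaks), so the
#' expected FRiP is `(1 - f) * q + f * rho` up to read-length edge
#' effects.
#'
#' @slot nReads read count.
#' @slot readLength bp.
#' @slot inPeakProbSignal probability `q` that a signal read lands in a
#'   peak.
#' @slot backgroundFraction background fraction `f`.
#' @slot seed integer seed.
#' @export
setClass("ReadGenSpec",
    representation(nReads = "integer", readLength = "integer",
                   inPeakProbSignal = "numeric",
                   backgroundFraction = "numeric", seed = "integer"),
    prototype(nReads = 10000L, readLength = 50L, inPeakProbSignal = 1,
              backgroundFraction = 0, seed = 1L)
)

setValidity("ReadGenSpec", function(object) {
    if (object@nReads < 1L) return("nReads must be positive")
    if (object@readLength < 1L) return("readLength must be positive")
    if (object@inPeakProbSignal < 0 || object@inPeakProbSignal > 1 ||
        object@backgroundFraction < 0 || object@backgroundFraction > 1)
        return("probabilities must lie in [0, 1]")
    TRUE
})

#' @rdname ReadGenSpec-class
#' @param nReads,readLength,inPeakProbSignal,backgroundFraction,seed see
#'   slots.
#' @export
ReadGenSpec <- function(nReads = 10000L, readLength = 50L,
                        inPeakProbSignal = 1, backgroundFraction = 0,
                        seed = 1L) {
    new("ReadGenSpec", nReads = as.integer(nReads),
        readLength = as.integer(readLength),
        inPeakProbSignal = inPeakProbSignal,
        backgroundFraction = backgroundFraction, seed = as.integer(seed))
}

#' Synthetic CTCF occupancy pool
#'
#' A synthetic stand-in for measured per-site CTCF occupancies: the `n`
#' evenly spaced quantiles of a Beta(1.5, 2.88) distribution (mean ~0.342,
#' wide spread), chosen so that iterative sampling to a target of 13 per
#' Mb draws about 38 sites — the site density of the baseline simulations.
#'
#' @param n pool size.
#' @return numeric vector of occupancies in (0, 1).
#' @export
defaultOccupancyPool <- function(n = 200L) {
    qbeta(((seq_len(n)) - 0.5) / n, 1.5, 2.88)
}

#' Generate a synthetic genome table
#'
#' @param nChroms,chromLength positive counts; chromosomes are named
#'   `chr1..chrN`, all of length `chromLength`.
#' @param seed accepted for interface uniformity (the table is
#'   deterministic).
#' @return named numeric vector of chromosome lengths.
#' @examples
#' genGenome(2, 5e5)
#' @export
genGenome <- function(nChroms, chromLength, seed = 1L) {
    .assertNumber(nChroms, "nChroms", 1)
    .assertNumber(chromLength, "chromLength", 1)
    setNames(rep(as.numeric(chromLength), nChroms),
             paste0("chr", seq_len(nChroms)))
}

#' Generate non-overlapping synthetic peaks
#'
#' Places `nPeaks` peaks of fixed width uniformly at random without
#' overlap, allocated across chromosomes proportionally to length, so that
#' the peak genome fraction is exactly `nPeaks * peakWidth / sum(genome)`.
#'
#' @param genome named numeric vector of chromosome lengths.
#' @param nPeaks,peakWidth peak count and width (bp);
#'   `nPeaks * peakWidth` must fit in the genome.
#' @param seed integer seed.
#' @return a `GRanges` of peaks.
#' @examples
#' g <- genGenome(1, 3e6)
#' p <- genPeaks(g, 80, 300, seed = 1)
#' peakGenomeFraction(p, g)  # 0.008
#' @export
genPeaks <- function(genome, nPeaks, peakWidth, seed = 1L) {
    .assertNumber(nPeaks, "nPeaks", 0)
    if (nPeaks == 0) return(GenomicRanges::GRanges())
    .assertNumber(peakWidth, "peakWidth", 1)
    # largest-remainder allocation proportional to chromosome length
    share <- nPeaks * genome / sum(genome)
    alloc <- floor(share)
    rem <- nPeaks - sum(alloc)
    if (rem > 0) {
        ord <- order(share - alloc, decreasing = TRUE)
        alloc[ord[seq_len(rem)]] <- alloc[ord[seq_len(rem)]] + 1
    }
    if (any(alloc * peakWidth > genome))
        stop("cannot pack ", nPeaks, " peaks of ", peakWidth,
             " bp into the genome")
    .withSeed(seed, {
        grs <- lapply(names(genome), function(chr) {
            k <- alloc[[chr]]
            if (k == 0) return(NULL)
            slack <- genome[[chr]] - k * peakWidth
            gaps <- sort(floor(runif(k) * (slack + 1)))
            starts0 <- gaps + (seq_len(k) - 1) * peakWidth  # 0-based
            GenomicRanges::GRanges(chr, IRanges::IRanges(
                start = starts0 + 1, width = peakWidth))
        })
        do.call(c, grs[!vapply(grs, is.null, logical(1))])
    })
}

#' Generate synthetic reads with controlled FRiP and background
#'
#' Draws `nReads` fixed-length reads: background reads (probability `f`)
#' start uniformly over the genome; signal reads land fully inside a
#' uniformly chosen peak with probability `q`, otherwise uniformly outside
#' peaks. The expected FRiP is `(1 - f) * q + f * rho` up to edge effects
#' smaller than `readLength / chromLength`.
#'
#' @param genome named numeric vector of chromosome lengths.
#' @param peaks a `GRanges` of peaks (equal widths recommended).
#' @param spec a [ReadGenSpec-class].
#' @return a `GRanges` of reads.
#' @export
genReads <- function(genome, peaks, spec) {
    stopifnot(is(spec, "ReadGenSpec"))
    validObject(spec)
    if (spec@readLength > min(genome))
        stop("readLength exceeds the shortest chromosome")
    n <- spec@nReads
    rl <- spec@readLength
    .withSeed(spec@seed, {
        isBg <- runif(n) < spec@backgroundFraction
        inPk <- !isBg & (runif(n) < spec@inPeakProbSignal) &
            length(peaks) > 0L
        chrom <- character(n)
        start <- numeric(n)

        uniformDraw <- function(k) {
            # uniform read starts over the whole genome (reads kept on-chrom)
            probs <- genome / sum(genome)
            ci <- sample.int(length(genome), k, replace = TRUE,
                             prob = probs)
            s <- floor(runif(k) * (genome[ci] - rl + 1)) + 1
            list(chrom = names(genome)[ci], start = s)
        }

        nBgLike <- sum(isBg)
        if (nBgLike > 0) {
            d <- uniformDraw(nBgLike)
            chrom[isBg] <- d$chrom
            start[isBg] <- d$start
        }
        nIn <- sum(inPk)
        if (nIn > 0) {
            pi <- sample.int(length(peaks), nIn, replace = TRUE)
            w <- GenomicRanges::width(peaks)[pi]
            off <- floor(runif(nIn) * pmax(1, w - rl + 1))
            chrom[inPk] <- as.character(
                GenomicRanges::seqnames(peaks))[pi]
            start[inPk] <- GenomicRanges::start(peaks)[pi] + off
        }
        isOut <- !isBg & !inPk
        nOut <- sum(isOut)
        if (nOut > 0) {
            # rejection-sample signal reads that avoid peaks entirely
            got <- 0
            chroms <- character(nOut)
            starts <- numeric(nOut)
            flat <- flattenIntervals(peaks)
            while (got < nOut) {
                k <- max(100L, 2L * (nOut - got))
                d <- uniformDraw(k)
                cand <- GenomicRanges::GRanges(
                    d$chrom, IRanges::IRanges(start = d$start, width = rl))
                ok <- GenomicRanges::countOverlaps(
                    cand, flat, ignore.strand = TRUE) == 0L
                take <- min(sum(ok), nOut - got)
                if (take > 0) {
                    sel <- which(ok)[seq_len(take)]
                    chroms[got + seq_len(take)] <- d$chrom[sel]
                    starts[got + seq_len(take)] <- d$start[sel]
                    got <- got + take
                }
            }
            chrom[isOut] <- chroms
            start[isOut] <- starts
        }
        GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start = start, width = rl))
    })
}

#' Generate a spike-in pair with known background and depletion
#'
#' Constructs calibrated counts obeying
#' `R_dep = R_UT * (f + gamma * (1 - f))`, optionally Poisson-sampled;
#' [estimateFUT()] on noiseless output recovers `f` exactly.
#'
#' @param rUTDepth calibrated read depth of the unperturbed sample.
#' @param trueF true background fraction in \[0, 1).
#' @param gamma remaining relative abundance in \[0, 1).
#' @param noise `"none"` or `"poisson"`.
#' @param seed integer seed (Poisson noise only).
#' @return a [SpikeInPair-class].
#' @examples
#' genSpikeinPair(1000, 0.3, 0)  # R_dep = 300
#' @export
genSpikeinPair <- function(rUTDepth, trueF, gamma,
                           noise = c("none", "poisson"), seed = 1L) {
    noise <- match.arg(noise)
    .assertNumber(rUTDepth, "rUTDepth", 0, strictLower = TRUE)
    .assertFraction(trueF, "trueF", allowOne = FALSE)
    .assertFraction(gamma, "gamma", allowOne = FALSE)
    depExp <- rUTDepth * (trueF + gamma * (1 - trueF))
    if (noise == "none") return(SpikeInPair(rUTDepth, depExp, gamma))
    .withSeed(seed, {
        rUT <- rpois(1L, rUTDepth)
        if (rUT == 0L) rUT <- 1L
        SpikeInPair(rUT, rpois(1L, depExp), gamma)
    })
}

#' Convert an in-silico profile to synthetic reads
#'
#' Samples read start sites proportional to the profile's leg counts on a
#' single-chromosome toy genome of `nSites * bpPerSite` bp; each read is
#' confined to its source lattice site, so interval FRiP over barrier
#' windows converges to [simulatedFrip()] as `nReads` grows.
#'
#' @param profile an [OccupancyProfile-class].
#' @param bpPerSite bp per lattice site; must be >= `readLength`.
#' @param nReads number of reads to draw.
#' @param readLength read length in bp.
#' @param seed integer seed.
#' @return list with elements `reads` (`GRanges` on chromosome
#'   `"chrSim"`) and `genome` (named length vector).
#' @export
profileToReads <- function(profile, bpPerSite = 250, nReads = 1e5,
                           readLength = 50, seed = 1L) {
    stopifnot(is(profile, "OccupancyProfile"))
    counts <- profile@legCounts
    if (sum(counts) == 0) stop("empty profile: no recorded legs")
    if (readLength > bpPerSite)
        stop("readLength must not exceed bpPerSite")
    nSites <- length(counts)
    .withSeed(seed, {
        sites <- sample.int(nSites, nReads, replace = TRUE,
                            prob = counts)
        off <- floor(runif(nReads) * (bpPerSite - readLength + 1))
        start <- (sites - 1) * bpPerSite + off + 1
        list(reads = GenomicRanges::GRanges(
                 "chrSim",
                 IRanges::IRanges(start = start, width = readLength)),
             genome = c(chrSim = nSites * bpPerSite))
    })
}

#' Barrier windows as genomic intervals
#'
#' Converts the tiled barrier windows of a simulation to intervals on the
#' `"chrSim"` toy genome used by [profileToReads()], for interval-based
#' FRiP.
#'
#' @param barriers a [BarrierSet-class].
#' @param window window half-width in sites.
#' @param bpPerSite bp per lattice site.
#' @param nReplicas replicas tiled.
#' @return a `GRanges` of window intervals.
#' @export
barrierWindowPeaks <- function(barriers, window = 1L, bpPerSite = 250,
                               nReplicas = 1L) {
    nSites <- nReplicas * barriers@sitesPerReplica
    idx <- .windowSiteIndex(barriers, as.integer(window), nReplicas,
                            nSites)
    if (length(idx) == 0L) return(GenomicRanges::GRanges())
    flattenIntervals(GenomicRanges::GRanges(
        "chrSim",
        IRanges::IRanges(start = (idx - 1) * bpPerSite + 1,
                         width = bpPerSite)))
}
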