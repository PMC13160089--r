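#' @include AllClasses.R utils.R barrier-kinetics.R
NULL

#' Construct simulation parameters
#'
#' Convenience constructor for [SimParams-class]; any field not supplied
#' keeps its default (the mESC-calibrated baseline: 25 replicas of 4000
#' sites at 250 bp, LEF separation 250 kb, lifetime 1300 s, birth rate 0.1,
#' pause rate 0, 4000 steps of 1 s, 25% burn-in, FRiP window 1).
#'
#' @param ... slot values overriding the defaults (see [SimParams-class]).
#' @return a validated [SimParams-class].
#' @examples
#' SimParams(seed = 7L, lefSeparationBp = 125000)
#' @export
SimParams <- function(...) {
    args <- list(...)
    intSlots <- c("sitesPerReplica", "nReplicas", "nSteps",
                  "snapshotStride", "fripWindow", "seed")
    for (s in intersect(names(args), intSlots))
        args[[s]] <- as.integer(args[[s]])
    do.call(new, c(list("SimParams"), args))
}

#' Number of extruders from the mean separation
#'
#' The extruder count on a lattice of `totalBp` basepairs with mean
#' extruder separation `lefSeparationBp` is
#' `max(1, round(totalBp / lefSeparationBp))`; at least one extruder is
#' always retained so depletion scans never empty the lattice.
#'
#' @param totalBp,lefSeparationBp positive lengths in bp.
#' @return integer extruder count.
#' @examples
#' nLefsFromSeparation(25e6, 250e3)  # 100
#' @export
nLefsFromSeparation <- function(totalBp, lefSeparationBp) {
    .assertNumber(totalBp, "totalBp", 0, strictLower = TRUE)
    .assertNumber(lefSeparationBp, "lefSeparationBp", 0, strictLower = TRUE)
    max(1L, as.integer(round(totalBp / lefSeparationBp)))
}

# Tile one replica's barrier layout across all replicas; returns 0-based
# global positions plus per-instance kinetics.
.tileBarriers <- function(barriers, nReplicas) {
    s <- barriers@sites
    n <- nrow(s)
    offs <- rep((seq_len(nReplicas) - 1L) * barriers@sitesPerReplica,
                each = n)
    list(position = rep(s$position, nReplicas) + offs,
         occupancy = rep(s$occupancy, nReplicas),
         bound_time = rep(s$bound_time_s, nReplicas),
         unbound_time = rep(s$unbound_time_s, nReplicas),
         orientation = rep(match(s$orientation, .ORIENTATIONS) - 1L,
                           nReplicas))
}

# Per-step switch probability for a mean dwell time (seconds):
# 1 - exp(-dt / tau); tau = 0 gives 1, tau = Inf gives 0.
.switchProb <- function(tau, dt) {
    p <- 1 - exp(-dt / tau)
    p[tau == 0] <- 1
    p
}

#' Run the 1D loop-extrusion simulation
#'
#' Simulates loop-extruding cohesins on a lattice of
#' `nReplicas * sitesPerReplica` sites with the barrier layout tiled across
#' replicas. Each step, barriers flip state, loaded extruders unload with a
#' lifetime-derived probability (the stalled lifetime applies when either
#' leg is stalled against a barrier or another extruder), unloaded
#' extruders reload at random free adjacent site pairs, and each leg steps
#' outward unless paused or blocked. Leg positions recorded after burn-in
#' are accumulated into an in-silico ChIP profile. Identical
#' (params, barriers, seed) give identical profiles.
#'
#' @param params a [SimParams-class].
#' @param barriers a [BarrierSet-class] defined on the same
#'   `sitesPerReplica`.
#' @return an [OccupancyProfile-class].
#' @examples
#' b <- homogeneousBarrierSet(seed = 1)
#' p <- SimParams(nReplicas = 2L, nSteps = 500L, seed = 1L)
#' prof <- simulateExtrusion(p, b)
#' simulatedFrip(prof, b)
#' @export
simulateExtrusion <- function(params, barriers) {
    stopifnot(is(params, "SimParams"), is(barriers, "BarrierSet"))
    validObject(params)
    validObject(barriers)
    if (barriers@sitesPerReplica != params@sitesPerReplica)
        stop("barrier set and SimParams disagree on sitesPerReplica")

    nSites <- params@nReplicas * params@sitesPerReplica
    totalBp <- nSites * params@bpPerSite
    nLefs <- nLefsFromSeparation(totalBp, params@lefSeparationBp)
    dt <- params@stepDuration
    tiled <- .tileBarriers(barriers, params@nReplicas)
    burnIn <- as.integer(floor(params@burnInFraction * params@nSteps))
    if (burnIn >= params@nSteps)
        stop("burn-in leaves no recorded snapshots")

    res <- .withSeed(params@seed, .simulate_cpp(
        nSites = nSites,
        barrierPos = as.integer(tiled$position),
        occupancy = tiled$occupancy,
        pUnbind = .switchProb(tiled$bound_time, dt),
        pBind = .switchProb(tiled$unbound_time, dt),
        orientation = as.integer(tiled$orientation),
        nLefs = nLefs,
        pDeath = .switchProb(params@lefLifetime, dt),
        pDeathStalled = .switchProb(params@lefStalledLifetime, dt),
        birthRate = params@lefBirthRate,
        pauseRate = params@lefPauseRate,
        nSteps = params@nSteps,
        burnInSteps = burnIn,
        stride = params@snapshotStride))

    new("OccupancyProfile",
        legCounts = res$leg_counts,
        nSnapshots = res$n_snapshots,
        nLefs = nLefs,
        sitesPerReplica = params@sitesPerReplica,
        nReplicas = params@nReplicas)
}

# 1-based indices of lattice sites within `window` of any tiled barrier.
.windowSiteIndex <- function(barriers, window, nReplicas, nSites) {
    pos <- .tileBarriers(barriers, nReplicas)$position
    if (length(pos) == 0L) return(integer(0))
    idx <- unique(as.vector(outer(pos, -window:window, `+`)))
    idx <- idx[idx >= 0L & idx < nSites]
    idx + 1L
}

#' Simulated FRiP of an occupancy profile
#'
#' The fraction of recorded cohesin legs within `window` lattice sites of a
#' barrier (window 1 means the barrier site plus the two flanking sites).
#' Overlapping windows are counted once.
#'
#' @param profile an [OccupancyProfile-class].
#' @param barriers the [BarrierSet-class] defining the windows.
#' @param window nonnegative window half-width in sites; defaults to 1.
#' @return fraction in \[0, 1\].
#' @export
simulatedFrip <- function(profile, barriers, window = 1L) {
    stopifnot(is(profile, "OccupancyProfile"), is(barriers, "BarrierSet"))
    .assertNumber(window, "window", 0)
    total <- sum(profile@legCounts)
    if (total == 0) stop("empty profile: no recorded legs")
    idx <- .windowSiteIndex(barriers, as.integer(window),
                            profile@nReplicas, length(profile@legCounts))
    if (length(idx) == 0L) return(0)
    sum(profile@legCounts[idx]) / total
}

#' Fraction of the lattice covered by barrier windows
#'
#' The union of barrier windows divided by the lattice size; the in-silico
#' analogue of the peak genome-fraction rho used in background adjustment.
#'
#' @inheritParams simulatedFrip
#' @param nReplicas replicas the layout is tiled over (windows never cross
#'   replica boundaries only through lattice edges, so per-replica coverage
#'   equals global coverage up to edge effects).
#' @return fraction in \[0, 1\].
#' @export
barrierWindowCoverage <- function(barriers, window = 1L, nReplicas = 1L) {
    stopifnot(is(barriers, "BarrierSet"))
    nSites <- nReplicas * barriers@sitesPerReplica
    length(.windowSiteIndex(barriers, as.integer(window), nReplicas,
                            nSites)) / nSites
}

.scanFrip <- function(params, barrierList, seeds) {
    nR <- length(barrierList)
    frips <- matrix(NA_real_, nR, length(seeds))
    for (i in seq_len(nR)) {
        for (j in seq_along(seeds)) {
            p <- initialize(params[[i]],
                            seed = .childSeed(seeds[[j]], i))
            prof <- simulateExtrusion(p, barrierList[[i]])
            frips[i, j] <- simulatedFrip(prof, barrierList[[i]],
                                         p@fripWindow)
        }
    }
    frips
}

#' Scan simulated FRiP against cohesin abundance
#'
#' For each abundance ratio `r` the extruder separation is set to
#' `baseline separation / r` (so `r` multiplies the extruder count), the
#' simulation is rerun over the seeds, and per-ratio mean and sd of
#' simulated FRiP are reported. With more extruders, collisions keep
#' individual cohesins from reaching barriers, so FRiP decreases with
#' abundance.
#'
#' @param abundanceRatios positive ratios relative to baseline (scans
#'   typically cover 0.1 to 2).
#' @param params baseline [SimParams-class].
#' @param barriers a [BarrierSet-class].
#' @param seeds integer vector of seeds; child seeds per (ratio, seed) are
#'   derived deterministically.
#' @return `data.frame` with columns `ratio`, `frip_mean`, `frip_sd`,
#'   `n_seeds`; the per-seed FRiP matrix is attached as attribute
#'   `"frips"`.
#' @export
scanCohesinAbundance <- function(abundanceRatios, params, barriers,
                                 seeds = 1:5) {
    if (any(abundanceRatios <= 0))
        stop("abundance ratios must be positive")
    paramsList <- lapply(abundanceRatios, function(r)
        initialize(params,
                   lefSeparationBp = params@lefSeparationBp / r))
    frips <- .scanFrip(paramsList,
                       rep(list(barriers), length(abundanceRatios)), seeds)
    .scanTable(abundanceRatios, frips, length(seeds))
}

#' Scan simulated FRiP against CTCF abundance
#'
#' Applies [scaleBarrierOccupancy()] per ratio and reports FRiP as in
#' [scanCohesinAbundance()]. More CTCF (higher occupancy) blocks extruders
#' more often, so FRiP increases with the ratio; ratio 0 gives the
#' no-barrier chance level.
#'
#' @param abundanceRatios nonnegative occupancy multipliers.
#' @inheritParams scanCohesinAbundance
#' @return as [scanCohesinAbundance()].
#' @export
scanCtcfAbundance <- function(abundanceRatios, params, barriers,
                              seeds = 1:5) {
    if (any(abundanceRatios < 0))
        stop("abundance ratios must be nonnegative")
    barrierList <- lapply(abundanceRatios, function(r)
        scaleBarrierOccupancy(barriers, r))
    frips <- .scanFrip(rep(list(params), length(abundanceRatios)),
                       barrierList, seeds)
    .scanTable(abundanceRatios, frips, length(seeds))
}

.scanTable <- function(ratios, frips, nSeeds) {
    out <- data.frame(
        ratio = ratios,
        frip_mean = rowMeans(frips),
        frip_sd = apply(frips, 1L, stats::sd),
        n_seeds = nSeeds)
    attr(out, "frips") <- frips
    out
}

#' Read/write occupancy profiles and scan tables as TSV
#'
#' Profiles are stored as two columns (`site`, `leg_count`); scan tables
#' with their full header row.
#'
#' @param profile an [OccupancyProfile-class]; `x` a scan `data.frame`.
#' @param path file path.
#' @param nLefs,nSnapshots,sitesPerReplica,nReplicas metadata for
#'   `readProfile` (the TSV stores only counts).
#' @return the written path (invisibly) or the object read.
#' @export
writeProfile <- function(profile, path) {
    stopifnot(is(profile, "OccupancyProfile"))
    write.table(
        data.frame(site = seq_along(profile@legCounts) - 1L,
                   leg_count = profile@legCounts),
        path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeProfile
#' @export
readProfile <- function(path, nLefs, nSnapshots, sitesPerReplica,
                        nReplicas) {
    df <- read.table(path, header = TRUE, sep = "\t")
    new("OccupancyProfile", legCounts = df$leg_count,
        nSnapshots = nSnapshots, nLefs = as.integer(nLefs),
        sitesPerReplica = as.integer(sitesPerReplica),
        nReplicas = as.integer(nReplicas))
}

#' @rdname writeProfile
#' @export
writeScanTable <- function(x, path) {
    write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeProfile
#' @export
readScanTable <- function(path) {
    read.table(path, header = TRUE, sep = "\t")
}
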