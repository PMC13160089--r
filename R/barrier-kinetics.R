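#' @include AllClasses.R utils.R
NULL

#' Convert bound/unbound dwell times to equilibrium occupancy
#'
#' A dynamic CTCF barrier alternates between a bound (blocking) state with
#' mean dwell time `boundTime` and an unbound (permissive) state with mean
#' dwell time `unboundTime`. Its equilibrium occupancy — the probability of
#' finding it bound — is `boundTime / (boundTime + unboundTime)`.
#'
#' @param boundTime,unboundTime nonnegative dwell times (any common unit);
#'   not both zero. `boundTime = Inf` gives occupancy 1.
#' @return occupancy in \[0, 1\].
#' @examples
#' occupancyFromTimes(780, 468)  # 0.625
#' @export
occupancyFromTimes <- function(boundTime, unboundTime) {
    if (any(boundTime < 0) || any(unboundTime < 0))
        stop("dwell times must be nonnegative")
    if (any(boundTime == 0 & unboundTime == 0))
        stop("boundTime and unboundTime cannot both be zero")
    ifelse(is.infinite(boundTime), 1, boundTime / (boundTime + unboundTime))
}

#' Convert occupancy to bound/unbound dwell times via an anchor
#'
#' Maps an occupancy to dwell times by holding the unbound time fixed at the
#' anchor's value, `u* = anchorBoundTime * (1 - anchorOccupancy) /
#' anchorOccupancy`, and scaling the bound time so that
#' `occupancyFromTimes()` of the result equals the requested occupancy.
#' Fixing the unbound time preserves the barrier's rebinding (search) rate
#' across occupancies while matching each target occupancy exactly; the
#' default anchor maps occupancy 0.65 to a bound time of 9.87 minutes.
#'
#' @param occupancy target occupancy in \[0, 1).
#' @param anchorOccupancy anchor occupancy in (0, 1).
#' @param anchorBoundTime anchor bound time (seconds by convention; the
#'   default is 9.87 minutes expressed in seconds).
#' @return named numeric vector `c(bound_time, unbound_time)` in the same
#'   unit as `anchorBoundTime`.
#' @examples
#' timesFromOccupancy(0.65)       # bound 592.2 s, unbound ~318.9 s
#' timesFromOccupancy(0.5)        # bound == unbound
#' @export
timesFromOccupancy <- function(occupancy, anchorOccupancy = 0.65,
                               anchorBoundTime = 9.87 * 60) {
    .assertFraction(occupancy, "occupancy", allowOne = FALSE)
    .assertNumber(anchorOccupancy, "anchorOccupancy", 0, 1,
                  strictLower = TRUE, strictUpper = TRUE)
    .assertNumber(anchorBoundTime, "anchorBoundTime", 0, strictLower = TRUE)
    uStar <- anchorBoundTime * (1 - anchorOccupancy) / anchorOccupancy
    c(bound_time = uStar * occupancy / (1 - occupancy),
      unbound_time = uStar)
}

.ORIENTATIONS <- c("bidirectional", "left-blocking", "right-blocking")

.makeBarrierSites <- function(position, occupancy, anchorOccupancy,
                              anchorBoundTime, orientation) {
    uStar <- anchorBoundTime * (1 - anchorOccupancy) / anchorOccupancy
    boundT <- ifelse(occupancy >= 1, Inf,
                     uStar * occupancy / (1 - occupancy))
    S4Vectors::DataFrame(
        position = as.integer(position),
        occupancy = as.numeric(occupancy),
        bound_time_s = boundT,
        unbound_time_s = rep(uStar, length(position)),
        orientation = rep(orientation, length.out = length(position))
    )
}

#' Sample a heterogeneous CTCF barrier set
#'
#' Draws per-site occupancies with replacement from a pool and assigns them
#' uniformly random distinct positions on a lattice replica, iterating until
#' the cumulative occupancy first reaches `targetOccupancyPerMb` (the
#' expected number of bound barriers per Mb; 13 at baseline). Dwell times
#' are derived from each occupancy through the anchor (see
#' [timesFromOccupancy()]).
#'
#' @param occupancyPool numeric vector of occupancies in (0, 1\]; see
#'   [defaultOccupancyPool()] for a synthetic pool.
#' @param targetOccupancyPerMb positive occupancy target per replica.
#' @param sitesPerReplica lattice sites per replica (default 4000,
#'   i.e. 1 Mb at 250 bp).
#' @param seed integer RNG seed.
#' @param anchorOccupancy,anchorBoundTime occupancy/dwell-time anchor.
#' @param orientation blocking orientation for all sites (default
#'   `"bidirectional"`).
#' @return a [BarrierSet-class].
#' @examples
#' b <- sampleBarrierSet(defaultOccupancyPool(), seed = 1)
#' nBarriers(b)
#' @export
sampleBarrierSet <- function(occupancyPool, targetOccupancyPerMb = 13,
                             sitesPerReplica = 4000L, seed = 1L,
                             anchorOccupancy = 0.65,
                             anchorBoundTime = 9.87 * 60,
                             orientation = "bidirectional") {
    if (length(occupancyPool) == 0L)
        stop("occupancyPool must be non-empty")
    if (any(occupancyPool < 0 | occupancyPool > 1))
        stop("occupancyPool entries must lie in [0, 1]")
    if (max(occupancyPool) <= 0)
        stop("target occupancy unreachable: pool contains only zeros")
    .assertNumber(targetOccupancyPerMb, "targetOccupancyPerMb", 0,
                  strictLower = TRUE)
    orientation <- match.arg(orientation, .ORIENTATIONS)

    draws <- .withSeed(seed, {
        occ <- numeric(0)
        total <- 0
        while (total < targetOccupancyPerMb) {
            x <- occupancyPool[sample.int(length(occupancyPool), 1L)]
            occ <- c(occ, x)
            total <- total + x
        }
        if (length(occ) > sitesPerReplica)
            stop("more sampled sites than lattice positions")
        pos <- sort(sample.int(sitesPerReplica, length(occ)) - 1L)
        list(occ = occ, pos = pos)
    })

    new("BarrierSet",
        sites = .makeBarrierSites(draws$pos, draws$occ, anchorOccupancy,
                                  anchorBoundTime, orientation),
        sitesPerReplica = as.integer(sitesPerReplica),
        targetOccupancyPerMb = targetOccupancyPerMb,
        anchorOccupancy = anchorOccupancy,
        anchorBoundTime = anchorBoundTime)
}

#' Construct a homogeneous CTCF barrier set
#'
#' All barriers share one bound time and one unbound time (defaults: CTCF
#' lifetime 780 s, off-time 468 s, i.e. occupancy 0.625). Site positions
#' are sampled uniformly; the site count follows the same stopping rule as
#' [sampleBarrierSet()], so with the defaults a target of 13 per Mb yields
#' `ceiling(13 / 0.625) = 21` sites.
#'
#' @param boundTime,unboundTime shared dwell times in seconds.
#' @inheritParams sampleBarrierSet
#' @return a [BarrierSet-class].
#' @examples
#' homogeneousBarrierSet(seed = 1)
#' @export
homogeneousBarrierSet <- function(boundTime = 780, unboundTime = 468,
                                  targetOccupancyPerMb = 13,
                                  sitesPerReplica = 4000L, seed = 1L,
                                  orientation = "bidirectional") {
    occ <- occupancyFromTimes(boundTime, unboundTime)
    if (occ <= 0 || occ >= 1)
        stop("homogeneous occupancy must lie in (0, 1)")
    sampleBarrierSet(occ, targetOccupancyPerMb, sitesPerReplica, seed,
                     anchorOccupancy = occ, anchorBoundTime = boundTime,
                     orientation = orientation)
}

#' Scale barrier occupancies (CTCF abundance change)
#'
#' Multiplies every occupancy by `factor` (capped at `1 - 1e-6` to keep
#' dwell times finite) and recomputes dwell times through the set's anchor;
#' positions and orientations are unchanged. Models a global change in CTCF
#' abundance.
#'
#' @param barriers a [BarrierSet-class].
#' @param factor nonnegative multiplier.
#' @return a new [BarrierSet-class].
#' @export
scaleBarrierOccupancy <- function(barriers, factor) {
    stopifnot(is(barriers, "BarrierSet"))
    .assertNumber(factor, "factor", 0)
    capped <- pmin(1 - 1e-6, barriers@sites$occupancy * factor)
    sites <- .makeBarrierSites(barriers@sites$position, capped,
                               barriers@anchorOccupancy,
                               barriers@anchorBoundTime,
                               barriers@sites$orientation)
    initialize(barriers, sites = sites)
}

#' Read/write barrier sets as TSV
#'
#' The on-disk format has columns `replica`, `position`, `occupancy`,
#' `bound_time_s`, `unbound_time_s`, `orientation`; one replica per file
#' (the simulator tiles it across replicas).
#'
#' @param barriers a [BarrierSet-class].
#' @param path file path.
#' @param sitesPerReplica,targetOccupancyPerMb,anchorOccupancy,anchorBoundTime
#'   metadata to attach on read (the TSV stores only per-site values).
#' @return `writeBarriers` returns `path` invisibly; `readBarriers` a
#'   [BarrierSet-class].
#' @export
writeBarriers <- function(barriers, path) {
    stopifnot(is(barriers, "BarrierSet"))
    df <- as.data.frame(barriers@sites)
    df <- cbind(replica = 0L, df)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeBarriers
#' @export
readBarriers <- function(path, sitesPerReplica = 4000L,
                         targetOccupancyPerMb = NA_real_,
                         anchorOccupancy = 0.65,
                         anchorBoundTime = 9.87 * 60) {
    df <- read.table(path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
    need <- c("position", "occupancy", "bound_time_s", "unbound_time_s",
              "orientation")
    if (!all(need %in% names(df)))
        stop("barrier TSV must have columns: replica, ",
             paste(need, collapse = ", "))
    if ("replica" %in% names(df) && length(unique(df$replica)) > 1L)
        stop("barrier TSV must describe a single replica")
    if (is.na(targetOccupancyPerMb))
        targetOccupancyPerMb <- sum(df$occupancy)
    new("BarrierSet",
        sites = S4Vectors::DataFrame(
            position = as.integer(df$position),
            occupancy = df$occupancy,
            bound_time_s = df$bound_time_s,
            unbound_time_s = df$unbound_time_s,
            orientation = df$orientation),
        sitesPerReplica = as.integer(sitesPerReplica),
        targetOccupancyPerMb = targetOccupancyPerMb,
        anchorOccupancy = anchorOccupancy,
        anchorBoundTime = anchorBoundTime)
}
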