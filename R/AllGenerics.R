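#' @include AllClasses.R
NULL

#' Accessors for BarrierSet
#'
#' @param x a [BarrierSet-class].
#' @return `barrierPositions`: integer vector of 0-based replica positions;
#'   `barrierOccupancy`: numeric occupancies; `nBarriers`: site count;
#'   `barrierSites`: the full `DataFrame`; `sitesPerReplica`: lattice size.
#' @name BarrierSet-accessors
#' @aliases barrierPositions barrierOccupancy nBarriers barrierSites
#'   sitesPerReplica
NULL

#' @rdname BarrierSet-accessors
#' @export
setGeneric("barrierPositions", function(x) standardGeneric("barrierPositions"))
#' @rdname BarrierSet-accessors
#' @export
setGeneric("barrierOccupancy", function(x) standardGeneric("barrierOccupancy"))
#' @rdname BarrierSet-accessors
#' @export
setGeneric("nBarriers", function(x) standardGeneric("nBarriers"))
#' @rdname BarrierSet-accessors
#' @export
setGeneric("barrierSites", function(x) standardGeneric("barrierSites"))
#' @rdname BarrierSet-accessors
#' @export
setGeneric("sitesPerReplica", function(x) standardGeneric("sitesPerReplica"))

#' @rdname BarrierSet-accessors
setMethod("barrierPositions", "BarrierSet", function(x) x@sites$position)
#' @rdname BarrierSet-accessors
setMethod("barrierOccupancy", "BarrierSet", function(x) x@sites$occupancy)
#' @rdname BarrierSet-accessors
setMethod("nBarriers", "BarrierSet", function(x) nrow(x@sites))
#' @rdname BarrierSet-accessors
setMethod("barrierSites", "BarrierSet", function(x) x@sites)
#' @rdname BarrierSet-accessors
setMethod("sitesPerReplica", "BarrierSet", function(x) x@sitesPerReplica)

#' Accessors for OccupancyProfile
#'
#' @param x an [OccupancyProfile-class].
#' @return `legCounts`: numeric vector of per-site leg counts;
#'   `nSnapshots`: recorded snapshot count.
#' @name OccupancyProfile-accessors
#' @aliases legCounts nSnapshots
NULL

#' @rdname OccupancyProfile-accessors
#' @export
setGeneric("legCounts", function(x) standardGeneric("legCounts"))
#' @rdname OccupancyProfile-accessors
#' @export
setGeneric("nSnapshots", function(x) standardGeneric("nSnapshots"))

#' @rdname OccupancyProfile-accessors
setMethod("legCounts", "OccupancyProfile", function(x) x@legCounts)
#' @rdname OccupancyProfile-accessors
setMethod("nSnapshots", "OccupancyProfile", function(x) x@nSnapshots)

setMethod("show", "BarrierSet", function(object) {
    cat(sprintf(
        "BarrierSet: %d sites on a %d-site replica (sum occupancy %.2f, target %.2f/Mb)\n",
        nBarriers(object), object@sitesPerReplica,
        sum(barrierOccupancy(object)), object@targetOccupancyPerMb))
    cat(sprintf("  anchor: occupancy %.3f -> bound time %.1f s\n",
                object@anchorOccupancy, object@anchorBoundTime))
})

setMethod("show", "SimParams", function(object) {
    totalBp <- object@nReplicas * object@sitesPerReplica * object@bpPerSite
    cat(sprintf(
        "SimParams: %d x %d sites (%.1f Mb at %g bp/site), %d LEFs\n",
        object@nReplicas, object@sitesPerReplica, totalBp / 1e6,
        object@bpPerSite,
        nLefsFromSeparation(totalBp, object@lefSeparationBp)))
    cat(sprintf(
        "  lifetime %g s (stalled %g s), birth %g, pause %g, %d steps, burn-in %g, seed %d\n",
        object@lefLifetime, object@lefStalledLifetime, object@lefBirthRate,
        object@lefPauseRate, object@nSteps, object@burnInFraction,
        object@seed))
})

setMethod("show", "OccupancyProfile", function(object) {
    cat(sprintf(
        "OccupancyProfile: %d sites, %g snapshots, %d LEFs, %.0f leg counts\n",
        length(object@legCounts), object@nSnapshots, object@nLefs,
        sum(object@legCounts)))
})

setMethod("show", "EquilibriumState", function(object) {
    cat(sprintf(
        "EquilibriumState: [A]=%.3e M of %.3e M total; [AC]=%.3e, [AB]=%.3e\n",
        object@aFree, object@aTotal, object@AC, object@AB))
    cat(sprintf("  alpha=%.4f, beta=%.4g\n", object@alpha, object@beta))
})

setMethod("show", "SpikeInPair", function(object) {
    cat(sprintf("SpikeInPair: R_UT=%.4g, R_dep=%.4g, gamma=%.3f\n",
                object@rUT, object@rDep, object@gamma))
})
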