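#' @include LoopFRiP-package.R
NULL

#' BarrierSet: dynamic CTCF barrier sites on a lattice replica
#'
#' Holds the CTCF barrier layout of one lattice replica: 0-based site
#' positions, equilibrium occupancies, the bound/unbound mean dwell times
#' (seconds) that realise those occupancies, and blocking orientations.
#' Occupancy is the equilibrium bound probability
#' `bound_time / (bound_time + unbound_time)`.
#'
#' @slot sites `DataFrame` with columns `position` (0-based lattice index),
#'   `occupancy` (probability), `bound_time_s`, `unbound_time_s` (seconds),
#'   `orientation` (one of `"bidirectional"`, `"left-blocking"`,
#'   `"right-blocking"`).
#' @slot sitesPerReplica integer, lattice sites per 1 Mb replica.
#' @slot targetOccupancyPerMb numeric, the summed-occupancy target the
#'   sampler stopped at (expected bound barriers per Mb).
#' @slot anchorOccupancy,anchorBoundTime numeric, the occupancy/bound-time
#'   anchor (seconds) used to convert occupancies to dwell times.
#'
#' @seealso [sampleBarrierSet()], [homogeneousBarrierSet()],
#'   [scaleBarrierOccupancy()]
#' @export
setClass("BarrierSet",
    representation(
        sites = "DataFrame",
        sitesPerReplica = "integer",
        targetOccupancyPerMb = "numeric",
        anchorOccupancy = "numeric",
        anchorBoundTime = "numeric"
    )
)

setValidity("BarrierSet", function(object) {
    s <- object@sites
    need <- c("position", "occupancy", "bound_time_s", "unbound_time_s",
              "orientation")
    if (!all(need %in% colnames(s)))
        return(paste("sites must have columns:", paste(need, collapse = ", ")))
    if (anyDuplicated(s$position))
        return("barrier positions must be unique within a replica")
    if (any(s$position < 0 | s$position >= object@sitesPerReplica))
        return("barrier position outside [0, sitesPerReplica)")
    if (any(s$occupancy < 0 | s$occupancy > 1))
        return("occupancy must lie in [0, 1]")
    if (any(s$bound_time_s < 0) || any(s$unbound_time_s < 0))
        return("dwell times must be nonnegative")
    ok <- s$orientation %in% c("bidirectional", "left-blocking",
                               "right-blocking")
    if (!all(ok)) return("unknown orientation value")
    mid <- s$occupancy > 0 & s$occupancy < 1
    if (any(mid)) {
        imp <- s$bound_time_s[mid] /
            (s$bound_time_s[mid] + s$unbound_time_s[mid])
        if (max(abs(imp - s$occupancy[mid])) > 1e-9)
            return("occupancy inconsistent with dwell times")
    }
    TRUE
})

#' SimParams: loop-extrusion simulation parameters
#'
#' Kinetic and lattice parameters for the 1D loop-extrusion simulation.
#' Defaults follow measurements in mouse embryonic stem cells: a 25 Mb
#' lattice (25 replicas of 1 Mb at 250 bp per site), loop-extruding factor
#' (LEF, i.e. cohesin) separation 250 kb, LEF lifetime 1300 s (same when
#' stalled), per-step birth probability 0.1, pause probability 0, 4000 steps
#' of 1 s with the first 25% discarded as burn-in, and a FRiP window of 1
#' lattice site on each side of a barrier.
#'
#' @slot sitesPerReplica,bpPerSite,nReplicas lattice geometry.
#' @slot lefSeparationBp mean genomic distance between extruders (bp); the
#'   extruder count is `max(1, round(totalBp / lefSeparationBp))`.
#' @slot lefLifetime,lefStalledLifetime mean extruder residence times (s).
#' @slot lefBirthRate,lefPauseRate per-step probabilities.
#' @slot stepDuration seconds per step.
#' @slot nSteps,burnInFraction,snapshotStride trajectory length, fraction of
#'   initial steps discarded, and recording stride after burn-in.
#' @slot fripWindow window half-width (sites) around each barrier for FRiP.
#' @slot seed integer RNG seed.
#' @export
setClass("SimParams",
    representation(
        sitesPerReplica = "integer",
        bpPerSite = "numeric",
        nReplicas = "integer",
        lefSeparationBp = "numeric",
        lefLifetime = "numeric",
        lefStalledLifetime = "numeric",
        lefBirthRate = "numeric",
        lefPauseRate = "numeric",
        stepDuration = "numeric",
        nSteps = "integer",
        burnInFraction = "numeric",
        snapshotStride = "integer",
        fripWindow = "integer",
        seed = "integer"
    ),
    prototype(
        sitesPerReplica = 4000L,
        bpPerSite = 250,
        nReplicas = 25L,
        lefSeparationBp = 250000,
        lefLifetime = 1300,
        lefStalledLifetime = 1300,
        lefBirthRate = 0.1,
        lefPauseRate = 0,
        stepDuration = 1,
        nSteps = 4000L,
        burnInFraction = 0.25,
        snapshotStride = 1L,
        fripWindow = 1L,
        seed = 1L
    )
)

setValidity("SimParams", function(object) {
    if (object@sitesPerReplica < 2L || object@nReplicas < 1L)
        return("lattice must have at least one replica of >= 2 sites")
    if (object@bpPerSite <= 0 || object@lefSeparationBp <= 0)
        return("bpPerSite and lefSeparationBp must be positive")
    if (object@lefLifetime <= 0 || object@lefStalledLifetime <= 0)
        return("lifetimes must be positive")
    if (object@lefBirthRate < 0 || object@lefBirthRate > 1 ||
        object@lefPauseRate < 0 || object@lefPauseRate > 1)
        return("birth/pause rates are per-step probabilities in [0, 1]")
    if (object@stepDuration <= 0) return("stepDuration must be positive")
    if (object@nSteps < 1L) return("nSteps must be >= 1")
    if (object@burnInFraction < 0 || object@burnInFraction >= 1)
        return("burnInFraction must lie in [0, 1)")
    if (object@snapshotStride < 1L) return("snapshotStride must be >= 1")
    if (object@fripWindow < 0L) return("fripWindow must be >= 0")
    TRUE
})

#' OccupancyProfile: aggregated cohesin leg counts (in-silico ChIP profile)
#'
#' Per-lattice-site counts of cohesin legs accumulated over all recorded
#' post-burn-in snapshots of a simulation; the in-silico analogue of a
#' ChIP-seq coverage profile.
#'
#' @slot legCounts numeric vector, one count per lattice site.
#' @slot nSnapshots number of recorded snapshots.
#' @slot nLefs number of extruders in the simulation.
#' @slot sitesPerReplica,nReplicas lattice geometry the profile lives on.
#' @export
setClass("OccupancyProfile",
    representation(
        legCounts = "numeric",
        nSnapshots = "numeric",
        nLefs = "integer",
        sitesPerReplica = "integer",
        nReplicas = "integer"
    )
)

setValidity("OccupancyProfile", function(object) {
    if (length(object@legCounts) !=
        object@sitesPerReplica * object@nReplicas)
        return("legCounts length must equal sitesPerReplica * nReplicas")
    if (any(object@legCounts < 0)) return("legCounts must be nonnegative")
    if (sum(object@legCounts) >
        2 * object@nLefs * object@nSnapshots + 1e-6)
        return("legCounts exceed 2 * nLefs * nSnapshots")
    TRUE
})

#' BiochemParams: reagent quantities and binding constants for the
#' antibody-background equilibrium model
#'
#' Reference values follow standard ChIP assay guidelines: chromatin
#' corresponding to 25 ug DNA, 5 ug IgG antibody (MW 150000 g/mol), 650
#' g/mol per DNA bp, in a 500 uL reaction. Dissociation constants and the
#' background-protein total default to illustrative values inside the
#' model's regime of validity (antibody in large excess over target).
#'
#' @slot dnaMass,antibodyMass grams.
#' @slot antibodyMw,bpMw g/mol (per molecule, per bp).
#' @slot reactionVolume liters.
#' @slot kdSpecific,kdNonspecific dissociation constants (molar) for
#'   antibody binding to chromatin-bound cohesin and to background proteins.
#' @slot bTotal total background-protein concentration (molar).
#' @slot loadedCohesinsPerMb expected loaded cohesins per Mb chromatin.
#' @slot epsilonReads additive technical noise reads (absorbed into the
#'   total-background constant theta; default 0).
#' @export
setClass("BiochemParams",
    representation(
        dnaMass = "numeric",
        antibodyMass = "numeric",
        antibodyMw = "numeric",
        bpMw = "numeric",
        reactionVolume = "numeric",
        kdSpecific = "numeric",
        kdNonspecific = "numeric",
        bTotal = "numeric",
        loadedCohesinsPerMb = "numeric",
        epsilonReads = "numeric"
    ),
    prototype(
        dnaMass = 25e-6,
        antibodyMass = 5e-6,
        antibodyMw = 150000,
        bpMw = 650,
        reactionVolume = 5e-4,
        kdSpecific = 1e-9,
        kdNonspecific = 1e-6,
        bTotal = 1e-9,
        loadedCohesinsPerMb = 4,
        epsilonReads = 0
    )
)

setValidity("BiochemParams", function(object) {
    pos <- c(object@dnaMass, object@antibodyMass, object@antibodyMw,
             object@bpMw, object@reactionVolume, object@kdSpecific,
             object@kdNonspecific)
    if (any(pos <= 0))
        return("masses, volume, molecular weights and Kds must be positive")
    if (object@bTotal < 0 || object@loadedCohesinsPerMb < 0 ||
        object@epsilonReads < 0)
        return("totals must be nonnegative")
    TRUE
})

#' EquilibriumState: solved antibody-binding equilibrium
#'
#' Concentrations (molar) at equilibrium for antibody (A) binding
#' chromatin-bound cohesin (C) and background proteins (B): free antibody,
#' totals, antibody-cohesin complex AC, antibody-background complex AB, the
#' antibody-bound proportion of cohesin (`alpha`) and the non-specific
#' binding ratio (`beta`).
#'
#' @slot aFree,aTotal,cTotal,AC,AB molar concentrations.
#' @slot alpha,beta fractions in \[0, 1\].
#' @export
setClass("EquilibriumState",
    representation(
        aFree = "numeric", aTotal = "numeric", cTotal = "numeric",
        AC = "numeric", AB = "numeric",
        alpha = "numeric", beta = "numeric"
    )
)

setValidity("EquilibriumState", function(object) {
    if (object@AC > object@cTotal * (1 + 1e-9))
        return("AC cannot exceed cTotal")
    if (object@alpha < 0 || object@alpha > 1 ||
        object@beta < 0 || object@beta > 1)
        return("alpha and beta must lie in [0, 1]")
    TRUE
})

#' BackgroundSpec: background model kind and magnitude
#'
#' @slot model `"uniform"` (non-specific antibody capture: total background
#'   reads constant in cohesin abundance) or `"proximal"` (proximal
#'   crosslinking: background scales with cohesin abundance, so its
#'   fraction is invariant under depletion).
#' @slot fBase baseline background fraction in [0, 1).
#' @slot theta total background reads (calibrated-read units).
#' @export
setClass("BackgroundSpec",
    representation(model = "character", fBase = "numeric", theta = "numeric"),
    prototype(model = "uniform", fBase = 0, theta = 0)
)

setValidity("BackgroundSpec", function(object) {
    if (!object@model %in% c("uniform", "proximal"))
        return("model must be 'uniform' or 'proximal'")
    if (object@fBase < 0 || object@fBase >= 1)
        return("fBase must lie in [0, 1)")
    if (object@theta < 0) return("theta must be nonnegative")
    TRUE
})

#' SpikeInPair: paired spike-in calibrated read counts
#'
#' Spike-in calibrated read counts for an unperturbed sample (`rUT`) and a
#' matched depleted sample (`rDep`), plus the relative cohesin abundance
#' remaining after depletion (`gamma`, externally measured).
#'
#' @slot rUT,rDep calibrated reads.
#' @slot gamma remaining relative abundance in [0, 1).
#' @export
setClass("SpikeInPair",
    representation(rUT = "numeric", rDep = "numeric", gamma = "numeric")
)

setValidity("SpikeInPair", function(object) {
    if (object@rUT <= 0) return("rUT must be positive")
    if (object@rDep < 0) return("rDep must be nonnegative")
    if (object@gamma < 0 || object@gamma >= 1)
        return("gamma must lie in [0, 1)")
    TRUE
})
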