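#' @include AllClasses.R utils.R extrusion-sim.R biochem-background.R
#' @include spikein-correction.R frip-intervals.R synth-fixtures.R
NULL

.COMMANDS <- list(
    simulate = c("sim", "barriers", "outdir", "seed"),
    `scan-cohesin` = c("sim", "barriers", "ratios", "n_seeds", "outdir",
                       "seed"),
    `scan-ctcf` = c("sim", "barriers", "ratios", "n_seeds", "outdir",
                    "seed"),
    adjust = c("scan_table", "f_base", "rho", "model", "outdir"),
    threshold = c("scan_table", "rho", "grid_step", "model", "outdir"),
    frip = c("reads", "peaks", "exclude", "genome", "outdir"),
    rho = c("peaks", "genome", "outdir"),
    `estimate-bg` = c("table", "outdir"),
    denoise = c("frip", "f", "rho", "outdir"),
    synth = c("n_chroms", "chrom_length", "n_peaks", "peak_width",
              "n_reads", "read_length", "q", "f", "outdir", "seed")
)

.SIM_KEYS <- c("sites_per_replica", "bp_per_site", "n_replicas",
               "lef_separation_bp", "lef_lifetime", "lef_stalled_lifetime",
               "lef_birth_rate", "lef_pause_rate", "step_duration",
               "n_steps", "burn_in_fraction", "snapshot_stride",
               "frip_window")

.BARRIER_KEYS <- c("mode", "path", "bound_time", "unbound_time",
                   "target_occupancy_per_mb", "occupancy_pool",
                   "anchor_occupancy", "anchor_bound_time")

.checkKeys <- function(x, allowed, where) {
    bad <- setdiff(names(x), allowed)
    if (length(bad))
        stop("unknown configuration key", if (length(bad) > 1) "s", " in ",
             where, ": ", paste(bad, collapse = ", "), call. = FALSE)
}

.simParamsFromConfig <- function(cfg, seed) {
    cfg <- cfg %||% list()
    .checkKeys(cfg, .SIM_KEYS, "sim")
    camel <- c(sites_per_replica = "sitesPerReplica",
               bp_per_site = "bpPerSite", n_replicas = "nReplicas",
               lef_separation_bp = "lefSeparationBp",
               lef_lifetime = "lefLifetime",
               lef_stalled_lifetime = "lefStalledLifetime",
               lef_birth_rate = "lefBirthRate",
               lef_pause_rate = "lefPauseRate",
               step_duration = "stepDuration", n_steps = "nSteps",
               burn_in_fraction = "burnInFraction",
               snapshot_stride = "snapshotStride",
               frip_window = "fripWindow")
    args <- setNames(cfg, camel[names(cfg)])
    do.call(SimParams, c(args, list(seed = seed)))
}

.barriersFromConfig <- function(cfg, sitesPerReplica, seed) {
    cfg <- cfg %||% list(mode = "homogeneous")
    .checkKeys(cfg, .BARRIER_KEYS, "barriers")
    mode <- cfg$mode %||% "homogeneous"
    switch(mode,
        file = readBarriers(cfg$path, sitesPerReplica = sitesPerReplica),
        homogeneous = homogeneousBarrierSet(
            boundTime = cfg$bound_time %||% 780,
            unboundTime = cfg$unbound_time %||% 468,
            targetOccupancyPerMb = cfg$target_occupancy_per_mb %||% 13,
            sitesPerReplica = sitesPerReplica,
            seed = .childSeed(seed, 101L)),
        heterogeneous = sampleBarrierSet(
            occupancyPool = unlist(cfg$occupancy_pool) %||%
                defaultOccupancyPool(),
            targetOccupancyPerMb = cfg$target_occupancy_per_mb %||% 13,
            sitesPerReplica = sitesPerReplica,
            seed = .childSeed(seed, 101L),
            anchorOccupancy = cfg$anchor_occupancy %||% 0.65,
            anchorBoundTime = cfg$anchor_bound_time %||% (9.87 * 60)),
        stop("unknown barrier mode: ", mode, call. = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.writeResolvedConfig <- function(command, config, outdir) {
    resolved <- c(list(command = command,
                       package_version =
                           as.character(packageVersion("LoopFRiP"))),
                  config)
    yaml::write_yaml(resolved, file.path(outdir, "run-config.yaml"))
}

#' Run a LoopFRiP command from a configuration
#'
#' Config-driven entry point binding the modules into reproducible runs;
#' the `loopfrip` script under `inst/scripts` is a thin shell wrapper
#' around this function. Unknown configuration keys are rejected with an
#' error naming the key; every run writes the resolved configuration
#' (`run-config.yaml`) next to its outputs, and all randomness derives
#' from the single `seed` entry.
#'
#' @param command one of `"simulate"`, `"scan-cohesin"`, `"scan-ctcf"`,
#'   `"adjust"`, `"threshold"`, `"frip"`, `"rho"`, `"estimate-bg"`,
#'   `"denoise"`, `"synth"`.
#' @param config named list of parameters, or the path of a YAML file
#'   holding one. Common keys: `outdir` (output directory, required),
#'   `seed` (root seed, default 1). Simulation commands take `sim` (a
#'   block of [SimParams-class] fields in snake_case) and `barriers`
#'   (`mode:` `"homogeneous"`, `"heterogeneous"` or `"file"` plus
#'   mode-specific keys). Interval commands take BED paths (`reads`,
#'   `peaks`, optional `exclude`) and a `genome` chrom.sizes path.
#' @return invisibly, a list of computed results (also written as TSV to
#'   `outdir`).
#' @export
runCommand <- function(command, config) {
    if (is.character(config) && length(config) == 1L)
        config <- yaml::read_yaml(config)
    if (!command %in% names(.COMMANDS))
        stop("unknown command: ", command, call. = FALSE)
    .checkKeys(config, .COMMANDS[[command]], command)
    outdir <- config$outdir
    if (is.null(outdir)) stop("config key 'outdir' is required")
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    seed <- as.integer(config$seed %||% 1L)

    out <- switch(command,
        simulate = {
            params <- .simParamsFromConfig(config$sim, seed)
            barriers <- .barriersFromConfig(config$barriers,
                                            params@sitesPerReplica, seed)
            prof <- simulateExtrusion(params, barriers)
            writeProfile(prof, file.path(outdir, "profile.tsv"))
            writeBarriers(barriers, file.path(outdir, "barriers.tsv"))
            list(profile = prof,
                 frip = simulatedFrip(prof, barriers, params@fripWindow))
        },
        `scan-cohesin` = ,
        `scan-ctcf` = {
            params <- .simParamsFromConfig(config$sim, seed)
            barriers <- .barriersFromConfig(config$barriers,
                                            params@sitesPerReplica, seed)
            ratios <- as.numeric(unlist(config$ratios))
            seeds <- .childSeed(seed, 1000L + seq_len(
                as.integer(config$n_seeds %||% 5L)))
            tab <- if (command == "scan-cohesin")
                scanCohesinAbundance(ratios, params, barriers, seeds)
            else scanCtcfAbundance(ratios, params, barriers, seeds)
            writeScanTable(tab, file.path(outdir, "scan.tsv"))
            list(scan = tab,
                 rho = barrierWindowCoverage(barriers,
                                             params@fripWindow))
        },
        adjust = {
            tab <- readScanTable(config$scan_table)
            adj <- backgroundAdjustedScan(tab,
                                          config$f_base %||% 0,
                                          config$rho,
                                          config$model %||% "uniform")
            writeScanTable(adj, file.path(outdir, "adjusted.tsv"))
            list(adjusted = adj)
        },
        threshold = {
            tab <- readScanTable(config$scan_table)
            grid <- seq(0, 0.95, by = config$grid_step %||% 0.05)
            thr <- monotonicInversionThreshold(
                tab, config$rho, grid, config$model %||% "uniform")
            writeScanTable(data.frame(threshold = thr),
                           file.path(outdir, "threshold.tsv"))
            list(threshold = thr)
        },
        frip = {
            reads <- readBed(config$reads)
            peaks <- readBed(config$peaks)
            excl <- if (!is.null(config$exclude)) readBed(config$exclude)
            st <- frip(reads, peaks, exclude = excl, details = TRUE)
            rho <- if (!is.null(config$genome))
                peakGenomeFraction(peaks, readChromSizes(config$genome))
            else NA_real_
            res <- data.frame(frip = st$frip, n_reads = st$n_reads,
                              n_in_peaks = st$n_in_peaks, rho = rho)
            writeScanTable(res, file.path(outdir, "frip.tsv"))
            list(frip = res)
        },
        rho = {
            peaks <- readBed(config$peaks)
            genome <- readChromSizes(config$genome)
            res <- data.frame(rho = peakGenomeFraction(peaks, genome))
            writeScanTable(res, file.path(outdir, "rho.tsv"))
            list(rho = res$rho)
        },
        `estimate-bg` = {
            tab <- read.table(config$table, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
            res <- estimateBackgroundTable(tab)
            writeScanTable(res, file.path(outdir, "background.tsv"))
            list(background = res)
        },
        denoise = {
            val <- denoiseFrip(config$frip, config$f, config$rho)
            writeScanTable(data.frame(frip_denoised = val),
                           file.path(outdir, "denoised.tsv"))
            list(frip_denoised = val)
        },
        synth = {
            genome <- genGenome(config$n_chroms %||% 1L,
                                config$chrom_length %||% 3e6)
            peaks <- genPeaks(genome, config$n_peaks %||% 80L,
                              config$peak_width %||% 300L,
                              seed = .childSeed(seed, 1L))
            spec <- ReadGenSpec(
                nReads = config$n_reads %||% 1e4,
                readLength = config$read_length %||% 50L,
                inPeakProbSignal = config$q %||% 1,
                backgroundFraction = config$f %||% 0,
                seed = .childSeed(seed, 2L))
            reads <- genReads(genome, peaks, spec)
            writeChromSizes(genome, file.path(outdir, "genome.chrom.sizes"))
            writeBed(peaks, file.path(outdir, "peaks.bed"))
            writeBed(reads, file.path(outdir, "reads.bed"))
            list(genome = genome, peaks = peaks, reads = reads)
        })
    .writeResolvedConfig(command, config, outdir)
    invisible(out)
}
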