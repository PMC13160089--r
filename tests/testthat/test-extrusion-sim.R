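test_that("extruder count follows separation with a floor of one", {
    expect_equal(nLefsFromSeparation(25e6, 250e3), 100L)
    expect_equal(nLefsFromSeparation(25e6, 25e6), 1L)
    expect_equal(nLefsFromSeparation(25e6, 50e6), 1L)
    expect_error(nLefsFromSeparation(0, 1), ">")
    expect_error(nLefsFromSeparation(1, -1), ">")
})

smallParams <- function(...) {
    SimParams(sitesPerReplica = 20L, nReplicas = 1L, bpPerSite = 250,
              lefSeparationBp = 20 * 250, ...)
}

test_that("a lone immortal extruder ends at the lattice boundaries", {
    p <- smallParams(lefLifetime = Inf, lefStalledLifetime = Inf,
                     lefBirthRate = 1, nSteps = 100L,
                     burnInFraction = 0.5, seed = 4L)
    prof <- simulateExtrusion(p, emptyBarrierSet(20L))
    counts <- legCounts(prof)
    # legs reach sites 0 and 19 within <= 20 steps and stay there
    expect_equal(sum(counts[2:19]), 0)
    expect_equal(counts[1], nSnapshots(prof))
    expect_equal(counts[20], nSnapshots(prof))
})

test_that("permanently bound barriers trap a lone extruder", {
    b <- manualBarrierSet(c(4L, 15L), c(1, 1), 20L)
    p <- smallParams(lefLifetime = Inf, lefStalledLifetime = Inf,
                     lefBirthRate = 1, nSteps = 200L,
                     burnInFraction = 0.5, seed = 3L)
    prof <- simulateExtrusion(p, b)
    counts <- legCounts(prof)
    # seed chosen so loading lands between the barriers; all recorded
    # legs then sit at the two sites flanking the bound barrier pair
    expect_gt(sum(counts[6:15]), 0)
    expect_equal(sum(counts[c(6, 15)]), sum(counts))
})

test_that("leg counts are conserved and runs are seed-reproducible", {
    b <- sampleBarrierSet(defaultOccupancyPool(), sitesPerReplica = 200L,
                          seed = 1)
    p <- SimParams(sitesPerReplica = 200L, nReplicas = 2L,
                   lefSeparationBp = 10000, nSteps = 400L, seed = 9L)
    prof <- simulateExtrusion(p, b)
    # each snapshot contributes exactly two counts per loaded extruder
    expect_lte(sum(legCounts(prof)), 2 * prof@nLefs * nSnapshots(prof))
    expect_equal(sum(legCounts(prof)) %% 2, 0)

    prof2 <- simulateExtrusion(p, b)
    expect_identical(legCounts(prof), legCounts(prof2))
    prof3 <- simulateExtrusion(initialize(p, seed = 10L), b)
    expect_false(identical(legCounts(prof), legCounts(prof3)))
})

test_that("long-run leg distribution matches the exact single-extruder chain", {
    n <- 12L
    tau <- 20
    pd <- 1 - exp(-1 / tau)
    p <- SimParams(sitesPerReplica = n, nReplicas = 1L,
                   lefSeparationBp = n * 250, lefLifetime = tau,
                   lefStalledLifetime = tau, lefBirthRate = 0.1,
                   nSteps = 200000L, burnInFraction = 0.25, seed = 21L)
    prof <- simulateExtrusion(p, emptyBarrierSet(n))
    sim <- legCounts(prof) / sum(legCounts(prof))
    exact <- singleLefStationaryProfile(n, pd, 0.1)
    expect_lt(max(abs(sim - exact)), 0.01)

    # chance-level FRiP against non-blocking dummy barriers equals the
    # window mass of the exact stationary profile
    dummy <- manualBarrierSet(c(3L, 8L), c(0, 0), n)
    fripSim <- simulatedFrip(prof, dummy, window = 1)
    fripExact <- sum(exact[c(3, 4, 5, 8, 9, 10)])
    expect_lt(abs(fripSim - fripExact), 0.02)
})

test_that("simulated FRiP counts window unions without double counting", {
    prof <- new("OccupancyProfile", legCounts = rep(1, 20),
                nSnapshots = 10, nLefs = 1L, sitesPerReplica = 20L,
                nReplicas = 1L)
    # k non-adjacent interior barriers, window 1, uniform profile -> 3k/n
    b <- manualBarrierSet(c(5L, 10L), c(0.5, 0.5), 20L)
    expect_equal(simulatedFrip(prof, b, window = 1), 6 / 20)
    # adjacent windows overlap and are unioned
    b2 <- manualBarrierSet(c(5L, 6L), c(0.5, 0.5), 20L)
    expect_equal(simulatedFrip(prof, b2, window = 1), 4 / 20)
    # all legs at barrier sites -> 1; no barriers -> 0
    delta <- new("OccupancyProfile",
                 legCounts = c(rep(0, 5), 10, rep(0, 14)),
                 nSnapshots = 5, nLefs = 1L, sitesPerReplica = 20L,
                 nReplicas = 1L)
    expect_equal(simulatedFrip(delta, manualBarrierSet(5L, 0.5, 20L),
                               window = 0), 1)
    expect_equal(simulatedFrip(prof, emptyBarrierSet(20L)), 0)
    empty <- new("OccupancyProfile", legCounts = rep(0, 20),
                 nSnapshots = 0, nLefs = 1L, sitesPerReplica = 20L,
                 nReplicas = 1L)
    expect_error(simulatedFrip(empty, b), "empty")

    expect_equal(barrierWindowCoverage(b, 1), 6 / 20)
})

test_that("abundance scans wire ratios to separation and occupancy", {
    b <- sampleBarrierSet(defaultOccupancyPool(), sitesPerReplica = 400L,
                          seed = 2, targetOccupancyPerMb = 4)
    p <- SimParams(sitesPerReplica = 400L, nReplicas = 2L,
                   lefSeparationBp = 20000, nSteps = 600L)
    sc <- scanCohesinAbundance(c(0.5, 1, 2), p, b, seeds = 1:3)
    expect_named(sc, c("ratio", "frip_mean", "frip_sd", "n_seeds"))
    expect_equal(sc$ratio, c(0.5, 1, 2))
    expect_true(all(sc$frip_mean >= 0 & sc$frip_mean <= 1))
    expect_equal(dim(attr(sc, "frips")), c(3L, 3L))
    expect_error(scanCohesinAbundance(c(-1, 1), p, b), "positive")

    ct <- scanCtcfAbundance(c(0, 1), p, b, seeds = 1:3)
    expect_equal(nrow(ct), 2L)
    # ratio 0 removes all blocking: FRiP near the chance level
    expect_lt(ct$frip_mean[1], ct$frip_mean[2])
    expect_error(scanCtcfAbundance(c(-0.5), p, b), "nonnegative")
})

test_that("profiles and scan tables roundtrip through TSV", {
    b <- homogeneousBarrierSet(sitesPerReplica = 100L, seed = 1,
                               targetOccupancyPerMb = 2)
    p <- SimParams(sitesPerReplica = 100L, nReplicas = 1L,
                   lefSeparationBp = 5000, nSteps = 200L, seed = 2L)
    prof <- simulateExtrusion(p, b)
    path <- withr::local_tempfile(fileext = ".tsv")
    writeProfile(prof, path)
    prof2 <- readProfile(path, nLefs = prof@nLefs,
                         nSnapshots = nSnapshots(prof),
                         sitesPerReplica = 100L, nReplicas = 1L)
    expect_equal(legCounts(prof2), legCounts(prof))

    sc <- data.frame(ratio = c(1, 2), frip_mean = c(0.5, 0.4),
                     frip_sd = c(0.01, 0.02), n_seeds = 3L)
    p2 <- withr::local_tempfile(fileext = ".tsv")
    writeScanTable(sc, p2)
    expect_equal(readScanTable(p2), sc)
})
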