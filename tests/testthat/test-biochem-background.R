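refParams <- new("BiochemParams")

test_that("molarity bookkeeping reproduces the reference reagent numbers", {
    # 5 ug IgG (MW 150000) in 500 uL
    expect_equal(concentrationFromMass(5e-6, 150000, 5e-4), 6.6667e-8,
                 tolerance = 1e-4)
    expect_equal(concentrationFromMass(150000, 150000, 1), 1)
    expect_error(concentrationFromMass(0, 1, 1), ">")

    # 25 ug DNA at 650 g/mol/bp in Mb equivalents
    mb <- countMegabaseEquivalents(25e-6, 650)
    expect_equal(mb, 2.3161538461e10, tolerance = 1e-10)
    expect_equal(countMegabaseEquivalents(50e-6, 650), 2 * mb)
    expect_equal(countMegabaseEquivalents(25e-6, 1300), mb / 2)

    # scale constant sigma and loaded-cohesin concentration
    sig <- sigmaScale(mb, 5e-4)
    expect_equal(sig, 7.692e-11, tolerance = 1e-4)
    expect_equal(sigmaScale(6.022e23 * 5e-4, 5e-4), 1)
    expect_equal(sigmaScale(mb, 1e-3), sig / 2)
    expect_equal(loadedCohesinConcentration(4, sig), 4 * sig)
    expect_equal(loadedCohesinConcentration(0, sig), 0)
    expect_equal(loadedCohesinConcentration(1, sig), sig)
})

test_that("bound CTCF density per Mb matches the abundance arithmetic", {
    expect_equal(round(boundSitesPerMb(217200, 0.49, 3 * 2700)), 13)
})

test_that("approximate equilibrium has the stated limiting behaviour", {
    # infinitely tight antibody: alpha -> 1, AC -> C_total
    tight <- initialize(refParams, kdSpecific = 1e-30)
    eq <- equilibriumApprox(tight)
    expect_equal(eq@alpha, 1, tolerance = 1e-12)
    expect_equal(eq@AC, eq@cTotal, tolerance = 1e-12)
    # no background protein: AB = 0
    eq0 <- equilibriumApprox(initialize(refParams, bTotal = 0))
    expect_equal(eq0@AB, 0)
    # Kd_s equal to total antibody: half saturation
    aTot <- concentrationFromMass(5e-6, 150000, 5e-4)
    eqH <- equilibriumApprox(initialize(refParams, kdSpecific = aTot))
    expect_equal(eqH@alpha, 0.5)
})

test_that("exact equilibrium conserves totals and matches the approximation", {
    eqE <- equilibriumExact(refParams)
    eqA <- equilibriumApprox(refParams)
    # antibody conservation to 1e-10 relative
    expect_equal(eqE@aFree + eqE@AC + eqE@AB, eqE@aTotal,
                 tolerance = 1e-10)
    # reference regime: cohesin is ~0.25% of antibody, so free antibody
    # stays within 3% of the total and the approximation within 0.5%
    expect_lte(eqE@cTotal / eqE@aTotal, 0.005)
    expect_gte(eqE@aFree / eqE@aTotal, 0.97)
    expect_equal(eqE@AC, eqA@AC, tolerance = 5e-3)
    expect_equal(eqE@AB, eqA@AB, tolerance = 5e-3)

    # degenerate: no targets at all leaves antibody free
    eq0 <- equilibriumExact(initialize(refParams,
                                       loadedCohesinsPerMb = 0,
                                       bTotal = 0))
    expect_equal(eq0@aFree, eq0@aTotal, tolerance = 1e-12)

    # symmetric case: equal Kds and totals give AC == AB
    sym <- initialize(refParams, kdNonspecific = refParams@kdSpecific)
    eqS <- equilibriumExact(sym)
    eqS2 <- equilibriumExact(initialize(sym,
        bTotal = eqS@cTotal))
    expect_equal(eqS2@AC, eqS2@AB, tolerance = 1e-9)
})

test_that("background-fraction rescaling follows the uniform model algebra", {
    expect_equal(thetaFromBaseline(0.5, 1000), 1000)
    expect_equal(thetaFromBaseline(0, 1000), 0)
    expect_equal(thetaFromBaseline(0.2, 1000), 250)
    expect_error(thetaFromBaseline(1, 10), "<")

    expect_equal(backgroundFractionAtAbundance(0.2, 1), 0.2)
    expect_equal(backgroundFractionAtAbundance(0.2, 1, "proximal"), 0.2)
    expect_equal(backgroundFractionAtAbundance(0.2, 0.5),
                 0.2 / (0.5 * 0.8 + 0.2))
    expect_equal(backgroundFractionAtAbundance(0.2, 3, "proximal"), 0.2)
    expect_error(backgroundFractionAtAbundance(0.2, 0), "positive")
    expect_equal(backgroundFractionAtAbundance(0.2, 0, limitAtZero = TRUE),
                 1)

    # limits and monotonicity of f(gamma)
    gam <- c(0.01, 0.1, 0.5, 1, 2, 10, 1000)
    f <- vapply(gam, backgroundFractionAtAbundance, numeric(1),
                fBase = 0.3)
    expect_true(all(diff(f) < 0))
    expect_lt(f[length(f)], 1e-3)
    expect_gt(backgroundFractionAtAbundance(0.3, 1e-9), 1 - 1e-6)
})

test_that("observed FRiP mixes signal and background linearly", {
    expect_equal(observedFrip(0.5, 0, 0.008), 0.5)
    expect_equal(observedFrip(0.008, 0.7, 0.008), 0.008)
    expect_equal(observedFrip(0.5, 0.4, 0.008), 0.3032)
    expect_error(observedFrip(1.2, 0, 0), "<=")
})

test_that("background adjustment of a scan reproduces its limits", {
    scan <- data.frame(ratio = c(0.1, 0.5, 1, 2),
                       frip_mean = c(0.62, 0.58, 0.55, 0.49))
    adj0 <- backgroundAdjustedScan(scan, 0, 0.0158)
    expect_equal(adj0$frip_adjusted, scan$frip_mean)
    expect_equal(adj0$f, rep(0, 4))

    # heavy uniform background inverts the trend
    adjH <- backgroundAdjustedScan(scan, 0.7, 0.0158)
    expect_true(all(diff(adjH$frip_adjusted) > 0))
    # proximal background preserves the decreasing trend at any level
    for (fb in c(0.2, 0.5, 0.8)) {
        adjP <- backgroundAdjustedScan(scan, fb, 0.0158, "proximal")
        expect_true(all(diff(adjP$frip_adjusted) < 0))
    }
})

test_that("inversion threshold search scans the grid minimally", {
    scan <- data.frame(ratio = c(0.1, 0.5, 1, 2),
                       frip_mean = c(0.62, 0.58, 0.55, 0.49))
    thr <- monotonicInversionThreshold(scan, 0.0158)
    grid <- seq(0, 0.95, by = 0.05)
    # returned value is on the grid and is minimal
    expect_true(thr %in% grid)
    below <- grid[grid < thr]
    for (fb in below) {
        adj <- backgroundAdjustedScan(scan, fb, 0.0158)
        expect_false(all(diff(adj$frip_adjusted) >= 0))
    }
    # flat raw scan: any positive background already increases adjusted
    flat <- data.frame(ratio = c(0.5, 1, 2), frip_mean = rep(0.4, 3))
    expect_equal(monotonicInversionThreshold(flat, 0.01), 0)
    # grid {0} cannot invert a strictly decreasing scan
    expect_true(is.na(monotonicInversionThreshold(scan, 0.0158,
                                                  fBaseGrid = 0)))
})
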