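#' @include AllClasses.R utils.R
NULL

#' Molar concentration from mass
#'
#' `mass / mw / volume`; e.g. 5 ug of IgG (MW 150000 g/mol) in 500 uL is
#' 6.67e-8 M.
#'
#' @param mass grams.
#' @param mw molecular weight, g/mol.
#' @param volume liters.
#' @return molar concentration.
#' @examples
#' concentrationFromMass(5e-6, 150000, 5e-4)
#' @export
concentrationFromMass <- function(mass, mw, volume) {
    .assertNumber(mass, "mass", 0, strictLower = TRUE)
    .assertNumber(mw, "mw", 0, strictLower = TRUE)
    .assertNumber(volume, "volume", 0, strictLower = TRUE)
    mass / mw / volume
}

#' Number of 1 Mb sequence equivalents in a chromatin mass
#'
#' `(dnaMass / bpMw) * N_A / 1e6` with Avogadro's number `N_A = 6.022e23`;
#' 25 ug DNA at 650 g/mol per bp contains about 2.316e10 Mb equivalents.
#'
#' @param dnaMass grams of DNA.
#' @param bpMw molecular weight per basepair, g/mol (default 650).
#' @return count of 1 Mb sequences.
#' @examples
#' countMegabaseEquivalents(25e-6)
#' @export
countMegabaseEquivalents <- function(dnaMass, bpMw = 650) {
    .assertNumber(dnaMass, "dnaMass", 0, strictLower = TRUE)
    .assertNumber(bpMw, "bpMw", 0, strictLower = TRUE)
    dnaMass / bpMw * .AVOGADRO / 1e6
}

#' Scale constant from per-Mb counts to molarity
#'
#' `sigma = mbCount / N_A / volume`: multiplying a per-Mb copy number by
#' `sigma` converts it to a molar concentration in the reaction volume.
#'
#' @param mbCount number of 1 Mb sequences in the reaction.
#' @param volume reaction volume in liters.
#' @return molar per (count per Mb).
#' @examples
#' sigmaScale(countMegabaseEquivalents(25e-6), 5e-4)
#' @export
sigmaScale <- function(mbCount, volume) {
    .assertNumber(mbCount, "mbCount", 0, strictLower = TRUE)
    .assertNumber(volume, "volume", 0, strictLower = TRUE)
    mbCount / .AVOGADRO / volume
}

#' Concentration of loaded cohesin from per-Mb abundance
#'
#' @param perMb loaded cohesins per Mb (nonnegative).
#' @param sigmaValue scale constant from [sigmaScale()].
#' @return molar concentration.
#' @export
loadedCohesinConcentration <- function(perMb, sigmaValue) {
    .assertNumber(perMb, "perMb", 0)
    .assertNumber(sigmaValue, "sigmaValue", 0, strictLower = TRUE)
    perMb * sigmaValue
}

.totalsFromParams <- function(params) {
    aTotal <- concentrationFromMass(params@antibodyMass, params@antibodyMw,
                                    params@reactionVolume)
    sig <- sigmaScale(countMegabaseEquivalents(params@dnaMass, params@bpMw),
                      params@reactionVolume)
    cTotal <- loadedCohesinConcentration(params@loadedCohesinsPerMb, sig)
    list(aTotal = aTotal, cTotal = cTotal)
}

#' Antibody-binding equilibrium, excess-antibody approximation
#'
#' Solves the antibody/cohesin/background binding equilibrium under the
#' model's working approximation that free antibody equals total antibody
#' (valid when antibody is in large excess over its targets, as with the
#' reference reagent quantities where cohesin is ~0.25% of antibody). Then
#' the antibody-bound proportion of cohesin is
#' `alpha = 1 / (Kd_s / [A] + 1)`, the antibody-cohesin complex is
#' `[AC] = [C_total] * alpha`, and the background complex is
#' `[AB] = [A] * beta` with the non-specific binding ratio
#' `beta = B_total / (Kd_n + [A])` — independent of cohesin abundance,
#' which is why total background reads are constant under depletion.
#'
#' @param params a [BiochemParams-class].
#' @return an [EquilibriumState-class].
#' @examples
#' equilibriumApprox(new("BiochemParams"))
#' @export
equilibriumApprox <- function(params) {
    stopifnot(is(params, "BiochemParams"))
    validObject(params)
    tot <- .totalsFromParams(params)
    aFree <- tot$aTotal
    alpha <- 1 / (params@kdSpecific / aFree + 1)
    beta <- params@bTotal / (params@kdNonspecific + aFree)
    new("EquilibriumState",
        aFree = aFree, aTotal = tot$aTotal, cTotal = tot$cTotal,
        AC = tot$cTotal * alpha, AB = aFree * beta,
        alpha = alpha, beta = beta)
}

#' Antibody-binding equilibrium, exact mass-action solution
#'
#' Solves the coupled mass-action and conservation equations for the free
#' antibody concentration by 1D root finding on
#' `[A] + C_total [A]/(Kd_s + [A]) + B_total [A]/(Kd_n + [A]) = A_total`,
#' then recovers all complex concentrations. Conservation residuals are
#' checked to 1e-10 relative.
#'
#' @param params a [BiochemParams-class].
#' @return an [EquilibriumState-class].
#' @export
equilibriumExact <- function(params) {
    stopifnot(is(params, "BiochemParams"))
    validObject(params)
    tot <- .totalsFromParams(params)
    aT <- tot$aTotal; cT <- tot$cTotal; bT <- params@bTotal
    ks <- params@kdSpecific; kn <- params@kdNonspecific
    g <- function(a) a + cT * a / (ks + a) + bT * a / (kn + a) - aT
    root <- uniroot(g, interval = c(0, aT), tol = aT * 1e-15,
                    extendInt = "no")
    a <- root$root
    AC <- cT * a / (ks + a)
    AB <- bT * a / (kn + a)
    resid <- abs(a + AC + AB - aT) / aT
    if (resid > 1e-10)
        stop(sprintf(
            "equilibrium solver did not converge (residual %.3e)", resid))
    new("EquilibriumState",
        aFree = a, aTotal = aT, cTotal = cT, AC = AC, AB = AB,
        alpha = if (cT > 0) AC / cT else 1 / (ks / a + 1),
        beta = bT / (kn + a))
}

#' Total background reads from a baseline background fraction
#'
#' Under the uniform background model the total background reads `theta`
#' are constant in cohesin abundance; given a baseline background fraction
#' `fBase` and the baseline cohesin reads (proportional to `[AC]`),
#' `theta = fBase / (1 - fBase) * acReads`.
#'
#' @param fBase baseline background fraction in \[0, 1).
#' @param acReads baseline cohesin-derived reads (calibrated units).
#' @return theta in the same units as `acReads`.
#' @examples
#' thetaFromBaseline(0.2, 1000)  # 250
#' @export
thetaFromBaseline <- function(fBase, acReads) {
    .assertFraction(fBase, "fBase", allowOne = FALSE)
    .assertNumber(acReads, "acReads", 0)
    fBase / (1 - fBase) * acReads
}

#' Background fraction after a change in cohesin abundance
#'
#' Under the uniform model total background reads are fixed while cohesin
#' reads scale with the relative abundance `gamma`, so the background
#' fraction becomes `fBase / (gamma * (1 - fBase) + fBase)`. Under the
#' proximal-crosslinking model background itself scales with cohesin
#' abundance, so the fraction is invariant and `fBase` is returned
#' unchanged.
#'
#' @param fBase baseline background fraction in \[0, 1).
#' @param gamma relative cohesin abundance versus baseline (> 0 for the
#'   uniform model unless `limitAtZero = TRUE`).
#' @param model `"uniform"` or `"proximal"`.
#' @param limitAtZero return the `gamma -> 0` limit (1 when `fBase > 0`)
#'   instead of erroring when `gamma = 0` under the uniform model.
#' @return background fraction in \[0, 1\].
#' @examples
#' backgroundFractionAtAbundance(0.2, 0.5)             # 1/3
#' backgroundFractionAtAbundance(0.2, 0.5, "proximal") # 0.2
#' @export
backgroundFractionAtAbundance <- function(fBase, gamma,
                                          model = c("uniform", "proximal"),
                                          limitAtZero = FALSE) {
    .assertFraction(fBase, "fBase", allowOne = FALSE)
    model <- match.arg(model)
    if (model == "proximal") return(fBase)
    if (gamma < 0 || (gamma == 0 && !limitAtZero))
        stop("gamma must be positive under the uniform model")
    if (gamma == 0) return(if (fBase > 0) 1 else 0)
    fBase / (gamma * (1 - fBase) + fBase)
}

#' Observed FRiP under a uniform background admixture
#'
#' Forward model of the denoising identity: a fraction `f` of reads is
#' uniform background landing in peaks with probability `rho`, so the
#' observed FRiP is `(1 - f) * fripTrue + f * rho`. Exactly inverted by
#' [denoiseFrip()].
#'
#' @param fripTrue background-free FRiP in \[0, 1\].
#' @param f background fraction in \[0, 1\].
#' @param rho peak genome fraction in \[0, 1\].
#' @return observed FRiP.
#' @examples
#' observedFrip(0.5, 0.4, 0.008)  # 0.3032
#' @export
observedFrip <- function(fripTrue, f, rho) {
    .assertFraction(fripTrue, "fripTrue")
    .assertFraction(f, "f")
    .assertFraction(rho, "rho")
    (1 - f) * fripTrue + f * rho
}

#' Background-adjust a simulated FRiP scan
#'
#' For each abundance ratio in a scan table, rescales the background
#' fraction via [backgroundFractionAtAbundance()] and applies
#' [observedFrip()], yielding the FRiP an experiment with baseline
#' background `fBase` would observe.
#'
#' @param scanTable `data.frame` with columns `ratio` and `frip_mean` (or
#'   `frip`), as returned by [scanCohesinAbundance()].
#' @param fBase baseline background fraction in \[0, 1).
#' @param rho peak (barrier-window) genome fraction; see
#'   [barrierWindowCoverage()].
#' @param model `"uniform"` or `"proximal"`.
#' @return `data.frame` with columns `ratio`, `f`, `frip_raw`,
#'   `frip_adjusted`.
#' @export
backgroundAdjustedScan <- function(scanTable, fBase, rho,
                                   model = c("uniform", "proximal")) {
    model <- match.arg(model)
    fripCol <- if ("frip_mean" %in% names(scanTable)) "frip_mean"
               else "frip"
    if (!all(c("ratio", fripCol) %in% names(scanTable)))
        stop("scanTable must have columns 'ratio' and 'frip_mean'/'frip'")
    f <- vapply(scanTable$ratio, backgroundFractionAtAbundance,
                numeric(1), fBase = fBase, model = model)
    raw <- scanTable[[fripCol]]
    adj <- mapply(observedFrip, fripTrue = raw, f = f,
                  MoreArgs = list(rho = rho))
    data.frame(ratio = scanTable$ratio, f = f, frip_raw = raw,
               frip_adjusted = adj)
}

#' Smallest baseline background fraction that inverts the FRiP trend
#'
#' Without background, simulated FRiP decreases with cohesin abundance;
#' sufficient uniform background inverts this because the background
#' fraction itself falls as abundance rises. This scans a grid of baseline
#' background fractions and returns the smallest one for which the
#' adjusted FRiP is nondecreasing across all consecutive abundance ratios
#' (around 0.35 under the baseline simulation conditions).
#'
#' @param scanTable cohesin-abundance scan covering ratios in \[0.1, 2\].
#' @param rho peak (barrier-window) genome fraction.
#' @param fBaseGrid ascending grid of baseline fractions (default step
#'   0.05).
#' @param model background model; the proximal model never inverts a
#'   decreasing scan.
#' @return the threshold fraction, or `NA` if no grid value yields a
#'   monotone increase.
#' @export
monotonicInversionThreshold <- function(scanTable, rho,
                                        fBaseGrid = seq(0, 0.95, by = 0.05),
                                        model = "uniform") {
    if (is.unsorted(fBaseGrid, strictly = TRUE))
        stop("fBaseGrid must be sorted ascending")
    ord <- order(scanTable$ratio)
    scanTable <- scanTable[ord, , drop = FALSE]
    for (fb in fBaseGrid) {
        adj <- backgroundAdjustedScan(scanTable, fb, rho, model)
        if (all(diff(adj$frip_adjusted) >= -1e-12)) return(fb)
    }
    NA_real_
}

#' Expected bound CTCF sites per Mb
#'
#' Converts a total protein copy number and chromatin-bound fraction to a
#' per-Mb density of bound sites over an effective genome length; e.g.
#' 217,200 CTCF molecules with 49% bound over 3 x 2.7 Gb gives ~13 per Mb.
#'
#' @param totalCopies total protein copies per cell.
#' @param boundFraction chromatin-bound fraction in \[0, 1\].
#' @param genomeMb effective genome length in Mb.
#' @return bound sites per Mb.
#' @examples
#' boundSitesPerMb(217200, 0.49, 3 * 2700)
#' @export
boundSitesPerMb <- function(totalCopies, boundFraction, genomeMb) {
    .assertNumber(totalCopies, "totalCopies", 0, strictLower = TRUE)
    .assertFraction(boundFraction, "boundFraction")
    .assertNumber(genomeMb, "genomeMb", 0, strictLower = TRUE)
    totalCopies * boundFraction / genomeMb
}
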