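#' @include AllClasses.R utils.R biochem-background.R
NULL

#' Construct a SpikeInPair
#'
#' @param rUT spike-in calibrated reads of the unperturbed sample (> 0).
#' @param rDep calibrated reads of the depleted sample (>= 0).
#' @param gamma relative cohesin abundance remaining after depletion, in
#'   \[0, 1); measured externally (e.g. quantitative western blot or
#'   imaging), never inferred here.
#' @return a [SpikeInPair-class].
#' @examples
#' SpikeInPair(100, 30, 0.1)
#' @export
SpikeInPair <- function(rUT, rDep, gamma = 0) {
    new("SpikeInPair", rUT = as.numeric(rUT), rDep = as.numeric(rDep),
        gamma = as.numeric(gamma))
}

#' Spike-in calibrated read count
#'
#' Scales a primary-genome read count by the inverse of the spike-in count:
#' `primary * scaleConstant / spikein` (reads per spike-in million by
#' default). Downstream estimators use only ratios of calibrated counts, so
#' the constant cancels.
#'
#' @param primaryCount reads mapped to the primary genome.
#' @param spikeinCount reads mapped to the spike-in genome (> 0).
#' @param scaleConstant scaling constant (default 1e6).
#' @return calibrated reads.
#' @examples
#' calibratedReads(5e6, 2.5e5)  # 2e7
#' @export
calibratedReads <- function(primaryCount, spikeinCount,
                            scaleConstant = 1e6) {
    .assertNumber(primaryCount, "primaryCount", 0)
    .assertNumber(spikeinCount, "spikeinCount", 0, strictLower = TRUE)
    .assertNumber(scaleConstant, "scaleConstant", 0, strictLower = TRUE)
    primaryCount * scaleConstant / spikeinCount
}

#' Estimate the unperturbed background fraction from a spike-in pair
#'
#' With calibrated reads `R_UT` (unperturbed) and `R_dep` (after depleting
#' the target to a remaining relative abundance `gamma`), the unperturbed
#' background fraction is `f_UT = (R_dep / R_UT - gamma) / (1 - gamma)`.
#' At `gamma = 0` (complete removal) this reduces to the simple calibrated
#' read ratio; ignoring a nonzero `gamma` overestimates the background
#' (see [naiveBackgroundEstimate()]).
#'
#' @param pair a [SpikeInPair-class].
#' @return background fraction estimate.
#' @examples
#' estimateFUT(SpikeInPair(100, 30, 0.1))  # 0.2222
#' @export
estimateFUT <- function(pair) {
    stopifnot(is(pair, "SpikeInPair"))
    validObject(pair)
    r <- pair@rDep / pair@rUT
    if (r < pair@gamma)
        stop(sprintf(
            "model violation: R_dep/R_UT = %.4g below gamma = %.4g", r,
            pair@gamma))
    (r - pair@gamma) / (1 - pair@gamma)
}

#' Naive background estimate ignoring residual target
#'
#' The plain calibrated read ratio `R_dep / R_UT`, which treats the
#' depletion as complete. For any residual abundance `gamma > 0` and true
#' background below 1 this strictly exceeds the [estimateFUT()] estimate.
#'
#' @param pair a [SpikeInPair-class].
#' @return ratio estimate.
#' @export
naiveBackgroundEstimate <- function(pair) {
    stopifnot(is(pair, "SpikeInPair"))
    validObject(pair)
    pair@rDep / pair@rUT
}

#' Background fraction of the depleted sample
#'
#' Rescales the unperturbed background fraction to the depleted condition:
#' `f_dep = f_UT / (gamma * (1 - f_UT) + f_UT)` (the uniform-background
#' rescaling applied at abundance `gamma`).
#'
#' @param fUT unperturbed background fraction in \[0, 1).
#' @param gamma remaining relative abundance (> 0).
#' @return background fraction of the depleted sample.
#' @examples
#' fDepFromFUT(0.2, 0.5)  # 1/3
#' @export
fDepFromFUT <- function(fUT, gamma) {
    if (gamma <= 0) stop("gamma must be positive")
    backgroundFractionAtAbundance(fUT, gamma, "uniform")
}

#' Denoise FRiP by removing the uniform background contribution
#'
#' Removes background reads from the numerator and denominator of FRiP:
#' `denoised = (fripObs - f * rho) / (1 - f)`, with `f` the background
#' fraction and `rho` the peak genome fraction. Values outside \[0, 1\]
#' are returned as-is with a warning, since they diagnose a mis-specified
#' `f` or `rho`.
#'
#' @param fripObs observed FRiP in \[0, 1\].
#' @param f background fraction in \[0, 1).
#' @param rho peak genome fraction in \[0, 1\].
#' @return denoised FRiP.
#' @examples
#' denoiseFrip(0.3032, 0.4, 0.008)  # 0.5
#' @export
denoiseFrip <- function(fripObs, f, rho) {
    .assertFraction(fripObs, "fripObs")
    .assertFraction(f, "f", allowOne = FALSE)
    .assertFraction(rho, "rho")
    out <- (fripObs - f * rho) / (1 - f)
    if (out < 0 || out > 1)
        warning(sprintf(
            "denoised FRiP %.4g outside [0, 1]: f or rho likely mis-specified",
            out))
    out
}

#' Batch background estimation and denoising
#'
#' Applies [estimateFUT()], [fDepFromFUT()] and (when `frip` and `rho`
#' columns are present) [denoiseFrip()] to each row of a sample table.
#'
#' @param x `data.frame` with columns `sample`, `R_UT`, `R_dep`, `gamma`,
#'   and optionally `frip`, `rho`.
#' @return the input with added columns `f_UT`, `f_dep` and (if
#'   applicable) `frip_denoised`.
#' @export
estimateBackgroundTable <- function(x) {
    need <- c("sample", "R_UT", "R_dep", "gamma")
    if (!all(need %in% names(x)))
        stop("need columns: ", paste(need, collapse = ", "))
    x$f_UT <- vapply(seq_len(nrow(x)), function(i)
        estimateFUT(SpikeInPair(x$R_UT[i], x$R_dep[i], x$gamma[i])),
        numeric(1))
    x$f_dep <- vapply(seq_len(nrow(x)), function(i)
        if (x$gamma[i] > 0) fDepFromFUT(x$f_UT[i], x$gamma[i])
        else if (x$f_UT[i] > 0) 1 else 0,
        numeric(1))
    if (all(c("frip", "rho") %in% names(x)))
        x$frip_denoised <- vapply(seq_len(nrow(x)), function(i)
            denoiseFrip(x$frip[i], x$f_UT[i], x$rho[i]), numeric(1))
    x
}
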