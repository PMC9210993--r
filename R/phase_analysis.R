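## Fourier statistics of periodic responses, direction-reversed run
## combination, and the cross-subject bivariate F-ratio.

#' Default noise band for the single-run F statistic
#'
#' All frequency indices `4 .. T/2 - 1`, excluding the stimulus index, its
#' second and third harmonics, and one neighbor on each side of every
#' excluded index. Indices 0--3 are dropped as slow drift (0--2 plus their
#' +1 neighbor) and the Nyquist index is dropped because its periodogram
#' ordinate has one rather than two degrees of freedom, which would bias
#' the F calibration.
#'
#' @param nTime number of time points `T`.
#' @param nCycles stimulus frequency index.
#' @return integer vector of noise frequency indices (cycles per run).
#' @export
defaultNoiseBand <- function(nTime, nCycles) {
    half <- nTime %/% 2L
    band <- seq.int(4L, half - 1L)
    excl <- as.vector(outer(nCycles * (1:3), -1:1, `+`))
    setdiff(band, excl)
}

#' Per-vertex Fourier phase, amplitude and significance of one run
#'
#' Computes, per vertex, the discrete Fourier coefficient at the stimulus
#' frequency. Amplitude uses the `2/T` scaling, so a pure cosine of
#' amplitude `a` returns `a`; phase 0 means a cosine peaking at `t = 0`
#' and a later response peak gives a more positive phase. Significance is
#' the ratio of signal power at the stimulus frequency to mean power over
#' the noise band: exactly `F(2, 2K)`-distributed under white noise for a
#' band of `K` frequencies. Vertices with constant time series are masked;
#' a noiseless periodic response yields the `Inf`/`p = 0` sentinel.
#'
#' @param run a [RunTimeSeries-class].
#' @param noiseBand integer vector of noise frequency indices, or `NULL`
#'   for [defaultNoiseBand()].
#' @return A [ComplexMapResult-class].
#' @export
fourierPhaseMap <- function(run, noiseBand = NULL) {
    stopifnot(is(run, "RunTimeSeries"))
    validObject(run)
    x <- runData(run)
    Tt <- ncol(x); k <- runCycles(run)
    if (k >= Tt %/% 2L) stop("nCycles out of range for ", Tt, " time points")
    if (is.null(noiseBand)) noiseBand <- defaultNoiseBand(Tt, k)
    noiseBand <- as.integer(noiseBand)
    if (length(noiseBand) < 1L) stop("empty noise band")
    if (any(noiseBand < 1L) || any(noiseBand > Tt %/% 2L))
        stop("noise band indices out of range")
    if (k %in% noiseBand) stop("stimulus index must not be in the noise band")
    X <- stats::mvfft(t(x))                      # T x N, rows = freq index 0..T-1
    coefK <- X[k + 1L, ]
    pSig <- Mod(coefK)^2
    pNoise <- Mod(X[noiseBand + 1L, , drop = FALSE])^2
    K <- length(noiseBand)
    mNoise <- colMeans(pNoise)
    defined <- apply(x, 1L, function(r) any(r != r[1]))
    F <- ifelse(mNoise > 0, pSig / mNoise, ifelse(pSig > 0, Inf, 0))
    p <- ifelse(is.infinite(F), 0, pf(F, 2, 2 * K, lower.tail = FALSE))
    ## 2/T amplitude scaling; phase = -Arg so later peaks map to positive phase
    coef <- (2 / Tt) * Conj(coefK)
    ComplexMapResult(coef = coef, fStat = F, dof = c(2, 2 * K),
                     pValue = p, mask = defined, nRuns = 1L)
}

#' Combine forward and time-reversed runs
#'
#' Every run's phase is first advanced by `2*pi*delayShiftS/periodS`
#' (compensating the estimated mean hemodynamic delay); reversed-run phases
#' are then negated (restoring the stimulus coordinate measured in reverse
#' order), and all runs are averaged as amplitude-weighted complex vectors.
#' Any hemodynamic delay common to forward and reversed runs cancels
#' exactly in the combined phase, whatever the shift: the residual delay
#' enters the two directions with opposite signs.
#'
#' @param forwardMaps,reversedMaps non-empty lists of
#'   [ComplexMapResult-class] from forward / time-reversed runs.
#' @param config a [ProtocolConfig-class]; supplies `delayShiftS`.
#' @param periodS stimulus period in seconds.
#' @return A [ComplexMapResult-class]. The combined F statistic is the mean
#'   of the per-run F values at their common degrees of freedom (a display
#'   heuristic; group inference should use [groupComplexFratio()]).
#' @export
combineReversed <- function(forwardMaps, reversedMaps, config, periodS) {
    if (length(forwardMaps) < 1L || length(reversedMaps) < 1L)
        stop("combination requires at least one run of each direction")
    stopifnot(is(config, "ProtocolConfig"))
    allMaps <- c(forwardMaps, reversedMaps)
    n <- length(mapCoef(allMaps[[1]]))
    for (m in allMaps) {
        stopifnot(is(m, "ComplexMapResult"))
        if (length(mapCoef(m)) != n) stop("maps differ in vertex count")
    }
    shift <- 2 * pi * config@delayShiftS / periodS
    adv <- exp(complex(real = 0, imaginary = -shift))
    corr <- c(lapply(forwardMaps, function(m) mapCoef(m) * adv),
              lapply(reversedMaps, function(m) Conj(mapCoef(m) * adv)))
    mask <- Reduce(`&`, lapply(allMaps, mapMask))
    coef <- Reduce(`+`, corr) / length(corr)
    Fs <- do.call(cbind, lapply(allMaps, fStat))
    F <- rowMeans(Fs)
    dof <- dofF(allMaps[[1]])
    p <- ifelse(is.infinite(F), 0, pf(F, dof[1], dof[2], lower.tail = FALSE))
    ComplexMapResult(coef = coef, fStat = F, dof = dof, pValue = p,
                     mask = mask, nRuns = length(allMaps))
}

#' Cross-subject complex average with bivariate F-ratio
#'
#' Treats each subject's per-vertex response as a bivariate (real,
#' imaginary) observation and tests whether the group mean vector differs
#' from zero under the isotropic bivariate normal model:
#' `F = (n-1) * n * |mean|^2 / sum(|deviation|^2)` with degrees of freedom
#' `(2, 2(n-1))`, which is exactly F-distributed under the null. The
#' combined phase is the angle of the mean vector. Zero dispersion yields
#' the `Inf`/`p = 0` sentinel.
#'
#' @param subjectMaps list of at least three [ComplexMapResult-class]
#'   objects on the same mesh.
#' @return A [ComplexMapResult-class] with `nRuns` = number of subjects.
#' @export
groupComplexFratio <- function(subjectMaps) {
    n <- length(subjectMaps)
    if (n < 3L) stop("need at least 3 subjects for the group F-ratio")
    nv <- length(mapCoef(subjectMaps[[1]]))
    Z <- do.call(cbind, lapply(subjectMaps, function(m) {
        stopifnot(is(m, "ComplexMapResult"))
        if (length(mapCoef(m)) != nv) stop("maps differ in vertex count")
        mapCoef(m)
    }))
    mask <- Reduce(`&`, lapply(subjectMaps, mapMask))
    zbar <- rowMeans(Z)
    dev <- rowSums(Mod(Z - zbar)^2)
    F <- ifelse(dev > 0, (n - 1) * n * Mod(zbar)^2 / dev,
                ifelse(Mod(zbar) > 0, Inf, 0))
    dof <- c(2, 2 * (n - 1))
    p <- ifelse(is.infinite(F), 0, pf(F, dof[1], dof[2], lower.tail = FALSE))
    ComplexMapResult(coef = zbar, fStat = F, dof = dof, pValue = p,
                     mask = mask, nRuns = n)
}
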