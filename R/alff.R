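#' @include AllClasses.R AllGenerics.R
NULL

#' Define a frequency band
#'
#' @param name band label.
#' @param lowHz,highHz closed band edges in Hz.
#' @return a \linkS4class{FrequencyBand}.
#' @export
frequencyBand <- function(name, lowHz, highHz) {
    new("FrequencyBand", name = name, lowHz = lowHz, highHz = highHz)
}

#' The five standard analysis bands
#'
#' The conventional low-frequency band and the four slow bands:
#' conventional 0.01-0.08 Hz, slow-5 0.01-0.027 Hz, slow-4 0.027-0.073 Hz,
#' slow-3 0.073-0.198 Hz, slow-2 0.198-0.25 Hz.  Touching edges are shared
#' (closed intervals); slow-2's upper edge equals the Nyquist frequency at
#' TR = 2 s.
#'
#' @param which optional subset of band names.
#' @return a named list of \linkS4class{FrequencyBand}s.
#' @export
standardBands <- function(which = c("conventional", "slow5", "slow4",
                                    "slow3", "slow2")) {
    all <- list(
        conventional = frequencyBand("conventional", 0.01, 0.08),
        slow5 = frequencyBand("slow5", 0.01, 0.027),
        slow4 = frequencyBand("slow4", 0.027, 0.073),
        slow3 = frequencyBand("slow3", 0.073, 0.198),
        slow2 = frequencyBand("slow2", 0.198, 0.25))
    all[match.arg(which, names(all), several.ok = TRUE)]
}

#' Remove a linear trend
#'
#' Subtracts the least-squares line (intercept + slope) from each series;
#' the output is orthogonal to both the constant and the linear regressor.
#'
#' @param series numeric vector, or matrix with one series per column
#'   (time in rows).
#' @return the detrended vector or matrix.
#' @export
detrendLinear <- function(series) {
    vec <- is.null(dim(series))
    y <- if (vec) matrix(series, ncol = 1L) else series
    n <- nrow(y)
    if (n < 3L)
        stop(errorCondition("need at least 3 time points to detrend",
                            class = "seriesLengthError"))
    x <- cbind(1, seq_len(n))
    res <- y - x %*% solve(crossprod(x), crossprod(x, y))
    if (vec) drop(res) else res
}

#' One-sided amplitude spectrum
#'
#' Computes, per series, the square-rooted periodogram under the
#' convention amplitude_k = (2/N)|X_k| for interior bins and (1/N)|X_k|
#' at DC and Nyquist, so a pure sinusoid of amplitude A at an exact bin
#' yields amplitude A there.  Frequencies are k/(N TR), k = 0..floor(N/2).
#'
#' @param series numeric vector, or matrix with one series per column.
#' @param trSeconds sampling interval in seconds.
#' @return list with \code{frequencies} (length floor(N/2)+1) and
#'   \code{amplitudes} (vector, or matrix with one column per series).
#' @export
amplitudeSpectrum <- function(series, trSeconds) {
    vec <- is.null(dim(series))
    y <- if (vec) matrix(series, ncol = 1L) else series
    n <- nrow(y)
    if (n < 4L)
        stop(errorCondition("need at least 4 time points",
                            class = "seriesLengthError"))
    if (any(!is.finite(y)))
        stop(errorCondition("non-finite values in series",
                            class = "nonFiniteError"))
    nk <- n %/% 2L + 1L
    X <- stats::mvfft(y)[seq_len(nk), , drop = FALSE]
    amp <- Mod(X) * (2 / n)
    amp[1L, ] <- amp[1L, ] / 2                       # DC
    if (n %% 2L == 0L) amp[nk, ] <- amp[nk, ] / 2    # Nyquist
    freqs <- (seq_len(nk) - 1L) / (n * trSeconds)
    list(frequencies = freqs,
         amplitudes = if (vec) drop(amp) else amp)
}

# indices of the spectrum bins falling in a closed band; errors if the
# band is empty, includes DC, or exceeds Nyquist
.bandBins <- function(frequencies, band) {
    sel <- which(frequencies >= band@lowHz - 1e-12 &
                 frequencies <= band@highHz + 1e-12)
    nyq <- frequencies[length(frequencies)]
    if (band@highHz > nyq + 1e-9)
        stop(errorCondition(
            sprintf("band %s [%g, %g] Hz exceeds the Nyquist frequency %.4g Hz",
                    band@name, band@lowHz, band@highHz, nyq),
            class = "emptyBandError"))
    if (!length(sel))
        stop(errorCondition(
            sprintf("no frequency bins in band %s [%g, %g] Hz (resolution %.5g Hz)",
                    band@name, band@lowHz, band@highHz,
                    frequencies[2L] - frequencies[1L]),
            class = "emptyBandError"))
    if (sel[1L] == 1L)
        stop(errorCondition(
            sprintf("band %s includes the DC bin; choose lowHz > 0", band@name),
            class = "dcBandError"))
    sel
}

#' Band-averaged amplitude (ALFF of one series)
#'
#' Arithmetic mean of the amplitude spectrum over the bins with
#' lowHz <= f <= highHz.
#'
#' @param frequencies,amplitudes as returned by
#'   \code{\link{amplitudeSpectrum}}.
#' @param band a \linkS4class{FrequencyBand}.
#' @return the scalar band amplitude (or one value per column).
#' @export
bandAlff <- function(frequencies, amplitudes, band) {
    sel <- .bandBins(frequencies, band)
    if (is.null(dim(amplitudes))) mean(amplitudes[sel])
    else colMeans(amplitudes[sel, , drop = FALSE])
}

#' Compute an ALFF map
#'
#' Per masked voxel: remove the linear trend, take the square-rooted FFT
#' power spectrum, and average it over the band.  Voxels outside the mask
#' are zero.
#'
#' @param vol a \linkS4class{TimeSeriesVolume} (already equilibrated, i.e.
#'   initial volumes discarded).
#' @param mask the analysis \linkS4class{BinaryMask}.
#' @param band a \linkS4class{FrequencyBand}.
#' @return an \linkS4class{AlffMap} (not normalized).
#' @export
alffMap <- function(vol, mask, band) {
    if (!all(dim(vol@data)[1:3] == mask@grid@shape))
        stop(errorCondition("volume and mask are on different grids",
                            class = "gridMismatchError"))
    nt <- dim(vol@data)[4L]
    if (nt < 4L)
        stop(errorCondition("need at least 4 time points",
                            class = "seriesLengthError"))
    sel <- which(mask@members)
    mat <- matrix(vol@data, ncol = nt)[sel, , drop = FALSE]   # voxels x time
    spec <- amplitudeSpectrum(detrendLinear(t(mat)), vol@trSeconds)
    vals <- bandAlff(spec$frequencies, spec$amplitudes, band)
    out <- array(0, dim = mask@grid@shape)
    out[sel] <- vals
    new("AlffMap", grid = vol@grid, values = out, band = band,
        normalized = FALSE)
}

#' Normalize an ALFF map (mALFF)
#'
#' Divides each masked value by the mean ALFF over the analysis mask, so
#' the masked mean becomes 1.  The same whole-brain-plus-eyeball mask used
#' for analysis is used for normalization.
#'
#' @param map an \linkS4class{AlffMap}.
#' @param mask the analysis \linkS4class{BinaryMask}.
#' @return the normalized \linkS4class{AlffMap}.
#' @export
normalizeAlff <- function(map, mask) {
    mu <- mean(map@values[mask@members])
    if (!is.finite(mu) || mu <= 0)
        stop(errorCondition("mask mean ALFF must be positive to normalize",
                            class = "normalizationError"))
    vals <- map@values / mu
    vals[!mask@members] <- 0
    new("AlffMap", grid = map@grid, values = vals, band = map@band,
        normalized = TRUE)
}
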