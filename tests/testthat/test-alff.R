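band5 <- standardBands()

test_that("linear detrending removes exactly the least-squares line", {
    t <- 1:100
    expect_equal(detrendLinear(3.5 - 0.2 * t), rep(0, 100))
    set.seed(4)
    x <- sin(2 * pi * 7 * (t - 1) / 100)
    got <- detrendLinear(x + 2 + 0.05 * t)
    expect_equal(got, detrendLinear(x), tolerance = 1e-10)
    # residuals orthogonal to [1, t]; idempotent
    expect_lt(abs(sum(got)), 1e-9)
    expect_lt(abs(sum(got * t)), 1e-7)
    expect_equal(detrendLinear(got), got, tolerance = 1e-12)
    expect_error(detrendLinear(c(1, 2)), class = "seriesLengthError")
    # matrix input detrends each column
    m <- cbind(1 + 2 * t, x)
    dm <- detrendLinear(m)
    expect_equal(dm[, 1], rep(0, 100))
    expect_equal(dm[, 2], detrendLinear(x))
})

test_that("amplitude spectrum matches the direct DFT oracle and the sinusoid identity", {
    set.seed(5)
    for (n in c(16, 63, 230, 256)) {
        x <- rnorm(n)
        got <- amplitudeSpectrum(x, 2)
        want <- dftAmplitudeOracle(x, 2)
        expect_equal(got$frequencies, want$frequencies)
        expect_lt(max(abs(got$amplitudes - want$amplitudes)), 1e-8)
    }
    # 3 sin(2 pi f t) at an exact bin of N=230, TR=2 -> amplitude 3 there
    n <- 230; tr <- 2; k <- 23
    x <- 3 * sin(2 * pi * (k / (n * tr)) * (0:(n - 1)) * tr)
    sp <- amplitudeSpectrum(x, tr)
    expect_equal(sp$amplitudes[k + 1], 3.0, tolerance = 1e-12)
    expect_lt(max(sp$amplitudes[-(k + 1)]), 1e-10)
    # zeros and scaling
    expect_true(all(amplitudeSpectrum(rep(0, 64), 2)$amplitudes == 0))
    expect_equal(amplitudeSpectrum(-2.5 * x, tr)$amplitudes,
                 2.5 * sp$amplitudes, tolerance = 1e-12)
    expect_error(amplitudeSpectrum(c(1, NA, 3, 4), 2),
                 class = "nonFiniteError")
})

test_that("Parseval: one-sided periodogram power equals the mean square", {
    set.seed(6)
    for (n in c(64, 101)) {
        x <- detrendLinear(rnorm(n))
        sp <- amplitudeSpectrum(x, 2)
        p <- sp$amplitudes^2 / 2                  # interior bins: A^2/2
        p[1] <- sp$amplitudes[1]^2                # DC
        if (n %% 2 == 0) p[length(p)] <- sp$amplitudes[length(p)]^2
        expect_equal(sum(p), mean(x^2), tolerance = 1e-8)
    }
})

test_that("band averaging uses closed intervals on the expected bins", {
    n <- 230; tr <- 2
    sp0 <- amplitudeSpectrum(rnorm(n), tr)
    # conventional band at resolution 1/460 Hz covers k = 5..36
    sel <- which(sp0$frequencies >= 0.01 - 1e-12 &
                 sp0$frequencies <= 0.08 + 1e-12)
    expect_equal(sel, (5:36) + 1)
    # single in-band sinusoid of amplitude 3 in a band of B = 32 bins
    x <- 3 * sin(2 * pi * (10 / (n * tr)) * (0:(n - 1)) * tr)
    sp <- amplitudeSpectrum(x, tr)
    expect_equal(bandAlff(sp$frequencies, sp$amplitudes, band5$conventional),
                 3 / 32, tolerance = 1e-10)
    # constant amplitudes average to themselves
    expect_equal(bandAlff(sp0$frequencies, rep(2.5, length(sp0$frequencies)),
                          band5$slow4), 2.5)
    # slow-2's upper edge is Nyquist at TR = 2 and is included
    sel2 <- which(sp0$frequencies >= 0.198 - 1e-12 &
                  sp0$frequencies <= 0.25 + 1e-12)
    expect_equal(max(sel2), length(sp0$frequencies))
    # empty and DC-containing bands are typed failures
    expect_error(bandAlff(sp0$frequencies, sp0$amplitudes,
                          frequencyBand("tooHigh", 0.3, 0.4)),
                 class = "emptyBandError")
    expect_error(bandAlff(c(0, 0.1, 0.2), c(1, 1, 1),
                          frequencyBand("narrow", 0.04, 0.06)),
                 class = "emptyBandError")
    expect_error(bandAlff(sp0$frequencies, sp0$amplitudes,
                          frequencyBand("dc", 0, 0.08)),
                 class = "dcBandError")
})

test_that("ALFF maps compose detrend, spectrum and band mean per masked voxel", {
    g <- volumeGridCreate(c(6, 6, 6))
    memb <- array(FALSE, c(6, 6, 6)); memb[2:5, 2:5, 2:5] <- TRUE
    mask <- binaryMask(memb, g)
    n <- 120
    x <- 2 * sin(2 * pi * (6 / (n * 2)) * (0:(n - 1)) * 2)   # in-band bin
    arr <- array(rep(x, each = 216), c(6, 6, 6, n))
    vol <- timeSeriesVolume(arr, g, trSeconds = 2)
    map <- alffMap(vol, mask, band5$conventional)
    inVals <- map@values[memb]
    expect_equal(max(inVals), min(inVals))        # constant inside
    expect_true(all(map@values[!memb] == 0))      # zero outside
    # equals the per-series composition detrend -> spectrum -> band mean
    sp <- amplitudeSpectrum(detrendLinear(x), 2)
    expect_equal(inVals[1], bandAlff(sp$frequencies, sp$amplitudes,
                                     band5$conventional), tolerance = 1e-12)
    # all-zero volume -> all-zero map
    z <- alffMap(timeSeriesVolume(array(0, c(6, 6, 6, 8)), g), mask,
                 band5$conventional)
    expect_true(all(z@values == 0))
    # ALFF unchanged by adding a linear trend (detrending precedes FFT)
    drift <- array(rep(0.3 * (1:n), each = 216), c(6, 6, 6, n))
    map2 <- alffMap(timeSeriesVolume(arr + drift, g, 2), mask,
                    band5$conventional)
    expect_equal(map2@values, map@values, tolerance = 1e-10)
})

test_that("planted in-band power raises regional ALFF above background", {
    set.seed(8)
    g <- volumeGridCreate(c(8, 8, 8))
    mask <- binaryMask(array(TRUE, c(8, 8, 8)), g)
    n <- 100
    arr <- array(rnorm(8^3 * n), c(8, 8, 8, n))
    sig <- 1.5 * sin(2 * pi * (8 / (n * 2)) * (0:(n - 1)) * 2 +
                     runif(1) * 2 * pi)
    for (i in 3:6) for (j in 3:6) for (k in 3:6)
        arr[i, j, k, ] <- arr[i, j, k, ] + sig
    map <- alffMap(timeSeriesVolume(arr, g, 2), mask, band5$conventional)
    reg <- array(FALSE, c(8, 8, 8)); reg[3:6, 3:6, 3:6] <- TRUE
    expect_gt(mean(map@values[reg]), mean(map@values[!reg]))
})

test_that("mALFF normalization has unit mask mean and is scale invariant", {
    g <- volumeGridCreate(c(5, 5, 5))
    memb <- array(FALSE, c(5, 5, 5)); memb[2:4, 2:4, 2:4] <- TRUE
    mask <- binaryMask(memb, g)
    m7 <- valuesAlffMap(array(7 * memb, c(5, 5, 5)), g)
    n7 <- normalizeAlff(m7, mask)
    expect_equal(unique(n7@values[memb]), 1)
    set.seed(9)
    vals <- array(abs(rnorm(125)) * memb, c(5, 5, 5))
    nm <- normalizeAlff(valuesAlffMap(vals, g), mask)
    expect_lt(abs(mean(nm@values[memb]) - 1), 1e-10)
    expect_true(nm@normalized)
    # scale invariance and idempotence
    nc <- normalizeAlff(valuesAlffMap(13.7 * vals, g), mask)
    expect_equal(nc@values, nm@values, tolerance = 1e-12)
    expect_equal(normalizeAlff(nm, mask)@values, nm@values, tolerance = 1e-12)
    zero <- valuesAlffMap(array(0, c(5, 5, 5)), g)
    expect_error(normalizeAlff(zero, mask), class = "normalizationError")
})
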