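#' @include AllClasses.R AllGenerics.R alff.R smoothing.R masks.R
NULL

# sphere of voxels (n x 3) around a 1-based center, intersected with a
# logical membership array
.sphereVoxels <- function(center, radiusMm, grid, members) {
    vox <- sphericalRoi(center, radiusMm, grid)
    keep <- members[vox]
    out <- vox[keep, , drop = FALSE]
    storage.mode(out) <- "integer"
    out
}

# coarse head geometry: an ellipsoid "brain" plus two anterior-inferior
# "eyeball" spheres; returns list(members, eyeCenters)
.headGeometry <- function(shape, voxelSize) {
    s <- shape
    ctr <- (s + 1) / 2
    ijk <- as.matrix(expand.grid(seq_len(s[1L]), seq_len(s[2L]), seq_len(s[3L])))
    semi <- 0.42 * s
    d2 <- ((ijk[, 1L] - ctr[1L]) / semi[1L])^2 +
          ((ijk[, 2L] - ctr[2L]) / semi[2L])^2 +
          ((ijk[, 3L] - ctr[3L]) / semi[3L])^2
    members <- array(d2 <= 1, dim = s)
    eyeZ <- max(1L, round(s[3L] * 0.25))
    eyeY <- min(s[2L], round(s[2L] * 0.92))
    eyeCenters <- rbind(c(round(s[1L] * 0.33), eyeY, eyeZ),
                        c(round(s[1L] * 0.67), eyeY, eyeZ))
    eyeR <- 2.2 * voxelSize[1L]
    for (i in 1:2) {
        off <- as.matrix(expand.grid(-3:3, -3:3, -3:3))
        cand <- sweep(off, 2L, eyeCenters[i, ], `+`)
        ok <- cand[, 1L] >= 1 & cand[, 1L] <= s[1L] &
              cand[, 2L] >= 1 & cand[, 2L] <= s[2L] &
              cand[, 3L] >= 1 & cand[, 3L] <= s[3L]
        cand <- cand[ok, , drop = FALSE]
        dd <- rowSums(sweep(cand, 2L, eyeCenters[i, ], `-`)^2) * voxelSize[1L]^2
        members[cand[dd <= eyeR^2, , drop = FALSE]] <- TRUE
    }
    list(members = members, eyeCenters = eyeCenters)
}

#' Create a synthetic-data configuration
#'
#' Defaults describe the stated synthetic world: a 24^3 grid of 3 mm
#' voxels, TR = 2 s, 240 time points, 20 subjects, 6 mm smoothing,
#' multiplicative lognormal subject baselines, and three planted
#' band-limited amplitude effects (sensorimotor-like higher in EC in the
#' conventional band, occipital-like higher in EO, and an eyeball sphere
#' with a high-band EO effect).  Pass \code{regions = list()} for a pure
#' null.
#'
#' @param shape,voxelSize,trSeconds,nTimepoints,nSubjects grid and
#'   acquisition parameters; see \linkS4class{SyntheticConfig}.
#' @param regions list of planted regions, or NULL for the defaults.
#' @param subjectSd,inbandAmp,noiseSd,driftSd,fwhmMm,siteShiftSd,seed
#'   generator parameters; see \linkS4class{SyntheticConfig}.
#' @return a \linkS4class{SyntheticConfig}.
#' @export
syntheticConfig <- function(shape = c(24L, 24L, 24L), voxelSize = c(3, 3, 3),
                            trSeconds = 2, nTimepoints = 240L,
                            nSubjects = 20L, regions = NULL,
                            subjectSd = 0.3, inbandAmp = 1, noiseSd = 1,
                            driftSd = 1, fwhmMm = 6, siteShiftSd = 0.2,
                            seed = 1L) {
    shape <- as.integer(shape)
    if (length(voxelSize) == 1L) voxelSize <- rep(voxelSize, 3L)
    if (is.null(regions)) {
        s <- shape
        geo <- .headGeometry(shape, voxelSize)
        regions <- list(
            list(name = "sensorimotor", favored = "EC", effect = 1.0,
                 band = frequencyBand("conventional", 0.01, 0.08),
                 center = c(round(s[1L] / 2), round(s[2L] * 0.4),
                            round(s[3L] * 0.75)),
                 radiusMm = 2.5 * voxelSize[1L]),
            list(name = "occipital", favored = "EO", effect = 1.0,
                 band = frequencyBand("conventional", 0.01, 0.08),
                 center = c(round(s[1L] / 2), round(s[2L] * 0.15),
                            round(s[3L] * 0.5)),
                 radiusMm = 2.5 * voxelSize[1L]),
            list(name = "eyeball", favored = "EO", effect = 1.0,
                 band = frequencyBand("slow3", 0.073, 0.198),
                 center = geo$eyeCenters[1L, ],
                 radiusMm = 2 * voxelSize[1L]))
    }
    new("SyntheticConfig", shape = shape, voxelSize = as.numeric(voxelSize),
        trSeconds = trSeconds, nTimepoints = as.integer(nTimepoints),
        nSubjects = as.integer(nSubjects), regions = regions,
        subjectSd = subjectSd, inbandAmp = inbandAmp, noiseSd = noiseSd,
        driftSd = driftSd, fwhmMm = fwhmMm, siteShiftSd = siteShiftSd,
        seed = as.integer(seed))
}

#' Generate a paired-condition synthetic dataset
#'
#' Per subject s and voxel v, each condition's time series is
#' g_s G_s(v) [broadband Gaussian noise + an in-band random-phase
#' sinusoidal mixture] + a linear drift, spatially smoothed at the
#' configured FWHM.  The multiplicative subject baseline (scalar gain g_s
#' times a smooth lognormal spatial field G_s) and the drift are shared
#' between a subject's EC and EO runs -- the within-subject pairing the
#' PAIR scheme exploits -- while phases and noise are condition-specific.
#' A planted region multiplies the per-bin amplitude of its band by
#' (1 + effect) in the favored condition.  Condition effects are amplitude
#' modulations, not mean shifts (mean shifts would vanish under
#' detrending).
#'
#' @param config a \linkS4class{SyntheticConfig}.
#' @param name dataset identifier.
#' @return a \linkS4class{PairedFmriDataset}; its \code{truth} slot lists
#'   each planted region's voxels, favored condition, effect and band.
#' @export
generatePairedDataset <- function(config, name = "synthetic") {
    rng <- .seededRng(config@seed)
    on.exit(rng$restore())
    grid <- volumeGridCreate(config@shape, config@voxelSize)
    geo <- .headGeometry(config@shape, config@voxelSize)
    mask <- new("BinaryMask", grid = grid, members = geo$members)
    sel <- which(geo$members)
    V <- prod(config@shape)
    N <- config@nTimepoints
    tr <- config@trSeconds

    # frequency support: everything from the lowest named band edge to
    # Nyquist carries the in-band floor
    kAll <- seq.int(ceiling(0.01 * N * tr), N %/% 2L)
    fAll <- kAll / (N * tr)

    truth <- lapply(config@regions, function(r) {
        vox <- .sphereVoxels(r$center, r$radiusMm, grid, geo$members)
        if (nrow(vox) == 0L)
            stop(errorCondition(paste("planted region", r$name,
                                      "falls outside the mask"),
                                class = "regionOutsideMaskError"))
        list(name = r$name, voxels = vox, favored = r$favored,
             effect = r$effect, band = r$band)
    })

    # per-condition amplitude profile: bins x voxels multiplier map
    ampFor <- function(cond) {
        amp <- matrix(config@inbandAmp, length(kAll), V)
        for (r in truth) {
            if (r$favored != cond) next
            bins <- which(fAll >= r$band@lowHz - 1e-12 &
                          fAll <= r$band@highHz + 1e-12)
            lin <- (r$voxels[, 3L] - 1L) * prod(config@shape[1:2]) +
                   (r$voxels[, 2L] - 1L) * config@shape[1L] + r$voxels[, 1L]
            amp[bins, lin] <- amp[bins, lin] * (1 + r$effect)
        }
        amp
    }
    ampEC <- ampFor("EC")
    ampEO <- ampFor("EO")

    makeRun <- function(amp, gainVec, drift) {
        Z <- matrix(0 + 0i, N, V)
        Z[kAll + 1L, ] <- amp * exp(2i * pi * matrix(stats::runif(length(amp)),
                                                     nrow(amp), ncol(amp)))
        ts <- Re(stats::mvfft(Z, inverse = TRUE))          # time x voxels
        ts <- ts + matrix(stats::rnorm(N * V, sd = config@noiseSd), N, V)
        ts <- ts * rep(gainVec, each = N)
        ts <- ts + outer((seq_len(N) - (N + 1) / 2) / N, drift)
        arr <- array(t(ts), dim = c(config@shape, N))
        arr <- gaussianSmooth(arr, config@fwhmMm, config@voxelSize)
        new("TimeSeriesVolume", grid = grid, data = arr, trSeconds = tr)
    }

    volsEC <- vector("list", config@nSubjects)
    volsEO <- vector("list", config@nSubjects)
    for (s in seq_len(config@nSubjects)) {
        g <- exp(stats::rnorm(1L, sd = config@subjectSd))
        field <- gaussianSmooth(array(stats::rnorm(V), dim = config@shape),
                                6 * config@voxelSize[1L], config@voxelSize)
        field <- field / stats::sd(field[sel]) * config@subjectSd
        gainVec <- g * exp(as.numeric(field))
        drift <- stats::rnorm(V, sd = config@driftSd)
        volsEC[[s]] <- makeRun(ampEC, gainVec, drift)
        volsEO[[s]] <- makeRun(ampEO, gainVec, drift)
    }
    new("PairedFmriDataset", volumesEC = volsEC, volumesEO = volsEO,
        mask = mask, truth = truth, name = name)
}

#' Generate a pair of synthetic "sites"
#'
#' Two datasets sharing the same planted region definitions but with
#' independently seeded subjects and site-specific overall signal and
#' noise levels (multiplicative lognormal shifts of log-SD
#' \code{siteShiftSd}), mimicking scanner differences between two imaging
#' centers.  With \code{siteShiftSeed} equal to the config seed and
#' \code{siteShiftSd = 0}, the two sites are identical.
#'
#' @param config a \linkS4class{SyntheticConfig} (used verbatim for site
#'   A).
#' @param siteShiftSeed seed for site B's subjects and level shifts.
#' @return list with elements \code{siteA} and \code{siteB}.
#' @export
makeSitePair <- function(config, siteShiftSeed = config@seed + 1000L) {
    siteA <- generatePairedDataset(config, name = "siteA")
    rng <- .seededRng(siteShiftSeed)
    shift <- exp(stats::rnorm(2L, sd = config@siteShiftSd))
    rng$restore()
    configB <- config
    configB@seed <- as.integer(siteShiftSeed)
    configB@inbandAmp <- config@inbandAmp * shift[1L]
    configB@noiseSd <- config@noiseSd * shift[2L]
    siteB <- generatePairedDataset(configB, name = "siteB")
    list(siteA = siteA, siteB = siteB)
}
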