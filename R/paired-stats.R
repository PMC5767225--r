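#' @include AllClasses.R AllGenerics.R masks.R
NULL

#' Voxel-wise paired t map
#'
#' For subject-aligned per-condition map lists, computes at every masked
#' voxel the paired t statistic t = mean(d) / (sd(d) / sqrt(m)) of the
#' within-subject differences d = C - O (sample sd, m - 1 denominator) --
#' identical to a one-sample t of the differences against zero.
#' Zero-variance voxels get t = 0 (with a message giving the count).
#'
#' @param mapsC,mapsO lists of \linkS4class{AlffMap}s for the two
#'   conditions (e.g. eyes closed and eyes open), same subject order.
#' @param mask the analysis \linkS4class{BinaryMask}.
#' @return a \linkS4class{PairedTMap} with df = m - 1.
#' @export
pairedTMap <- function(mapsC, mapsO, mask) {
    m <- length(mapsC)
    if (length(mapsO) != m)
        stop(errorCondition("condition lists must have equal length",
                            class = "subjectAlignmentError"))
    if (m < 2L)
        stop(errorCondition("need at least 2 subjects for a paired t-test",
                            class = "sampleSizeError"))
    sel <- which(mask@members)
    d <- vapply(seq_len(m),
                function(i) mapsC[[i]]@values[sel] - mapsO[[i]]@values[sel],
                numeric(length(sel)))               # voxels x subjects
    mu <- rowMeans(d)
    ss <- rowSums((d - mu)^2)
    sdv <- sqrt(ss / (m - 1L))
    tv <- ifelse(sdv > 0, mu / (sdv / sqrt(m)), 0)
    nzero <- sum(sdv == 0)
    if (nzero > 0L)
        message(nzero, " zero-variance voxels set to t = 0")
    out <- array(0, dim = mask@grid@shape)
    out[sel] <- tv
    new("PairedTMap", grid = mask@grid, values = out, df = m - 1L)
}

#' Two-sided voxel t threshold from p
#'
#' The critical value such that |t| exceeds it with probability p under
#' Student's t with \code{df} degrees of freedom (two-sided).
#'
#' @param p voxel-wise two-sided p threshold (default 0.01).
#' @param df degrees of freedom.
#' @return the positive critical t value.
#' @export
voxelThresholdFromP <- function(p = 0.01, df) {
    if (p <= 0 || p >= 1) stop("p must be in (0, 1)")
    if (df < 1) stop("df must be >= 1")
    stats::qt(1 - p / 2, df)
}

# connected components of a voxel set (n x 3 index matrix) under
# 26-connectivity; returns an integer component id per row
.connectedComponents26 <- function(vox, shape) {
    n <- nrow(vox)
    if (n == 0L) return(integer(0))
    lin <- (vox[, 3L] - 1L) * (shape[1L] * shape[2L]) +
           (vox[, 2L] - 1L) * shape[1L] + vox[, 1L]
    off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    off <- off[rowSums(abs(off)) > 0L, , drop = FALSE]
    edges <- NULL
    for (j in seq_len(nrow(off))) {
        nb <- sweep(vox, 2L, off[j, ], `+`)
        ok <- nb[, 1L] >= 1L & nb[, 1L] <= shape[1L] &
              nb[, 2L] >= 1L & nb[, 2L] <= shape[2L] &
              nb[, 3L] >= 1L & nb[, 3L] <= shape[3L]
        if (!any(ok)) next
        nbl <- (nb[ok, 3L] - 1L) * (shape[1L] * shape[2L]) +
               (nb[ok, 2L] - 1L) * shape[1L] + nb[ok, 1L]
        hit <- match(nbl, lin)
        found <- !is.na(hit)
        if (any(found))
            edges <- rbind(edges, cbind(which(ok)[found], hit[found]))
    }
    g <- igraph::graph_from_edgelist(
        if (is.null(edges)) matrix(integer(0), 0, 2) else edges,
        directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
    igraph::components(g)$membership[seq_len(n)]
}

#' Label supra-threshold clusters
#'
#' Thresholds a paired-t map two-sidedly at \code{tCrit}, labels positive
#' and negative supra-threshold voxels separately by 26-connectivity
#' (faces, edges, corners) connected components, discards components
#' smaller than \code{minExtentVoxels}, and summarizes each surviving
#' cluster (extent, peak, ROI mean t over the \code{roiRadiusMm} sphere at
#' the peak).  Clusters are ordered by descending extent, then descending
#' |peak t|; peak ties go to the lowest linear voxel index.
#'
#' An extent threshold given in mm^3 converts to
#' ceiling(mm3 / voxel volume) voxels; 1269 mm^3 on a 3 mm isotropic grid
#' is 47 voxels, and clusters of exactly 47 voxels survive
#' (extent >= minExtentVoxels).
#'
#' @param tmap a \linkS4class{PairedTMap}.
#' @param mask the analysis \linkS4class{BinaryMask}.
#' @param tCrit positive voxel threshold on |t|.
#' @param minExtentVoxels minimal cluster extent in voxels (default 47).
#' @param minExtentMm3 alternatively, minimal extent in mm^3 (overrides
#'   \code{minExtentVoxels} when given).
#' @param roiRadiusMm radius of the peak ROI used for roiMeanT (default 5).
#' @return a \linkS4class{ClusterSet} (possibly empty).
#' @export
labelClusters <- function(tmap, mask, tCrit, minExtentVoxels = 47L,
                          minExtentMm3 = NULL, roiRadiusMm = 5) {
    if (tCrit <= 0) stop("tCrit must be > 0")
    voxVol <- prod(mask@grid@voxelSize)
    if (!is.null(minExtentMm3))
        minExtentVoxels <- as.integer(ceiling(minExtentMm3 / voxVol))
    if (minExtentVoxels < 1L) stop("minimum extent must be >= 1 voxel")
    shape <- mask@grid@shape
    labels <- array(0L, dim = shape)
    rows <- list()
    comps <- list()
    for (sgn in c(1, -1)) {
        supra <- mask@members & (sgn * tmap@values >= tCrit)
        vox <- which(supra, arr.ind = TRUE)
        if (nrow(vox) == 0L) next
        membership <- .connectedComponents26(vox, shape)
        for (cid in unique(membership)) {
            mem <- vox[membership == cid, , drop = FALSE]
            if (nrow(mem) < minExtentVoxels) next
            tvals <- tmap@values[mem]
            lin <- (mem[, 3L] - 1L) * (shape[1L] * shape[2L]) +
                   (mem[, 2L] - 1L) * shape[1L] + mem[, 1L]
            best <- which(abs(tvals) == max(abs(tvals)))
            best <- best[which.min(lin[best])]      # deterministic tie-break
            peak <- mem[best, ]
            roi <- suppressWarnings(
                sphericalRoi(peak, roiRadiusMm, mask@grid, mask))
            comps[[length(comps) + 1L]] <- mem
            rows[[length(rows) + 1L]] <- data.frame(
                sign = sgn, extentVoxels = nrow(mem),
                extentMm3 = nrow(mem) * voxVol,
                peakI = peak[1L], peakJ = peak[2L], peakK = peak[3L],
                peakXmm = NA_real_, peakYmm = NA_real_, peakZmm = NA_real_,
                peakT = tvals[best],
                roiMeanT = mean(tmap@values[roi]))
        }
    }
    if (length(rows)) {
        tab <- do.call(rbind, rows)
        mm <- voxelToMm(mask@grid,
                        as.matrix(tab[, c("peakI", "peakJ", "peakK")]))
        tab$peakXmm <- mm[, 1L]; tab$peakYmm <- mm[, 2L]; tab$peakZmm <- mm[, 3L]
        ord <- order(-tab$extentVoxels, -abs(tab$peakT),
                     (tab$peakK - 1L) * prod(shape[1:2]) +
                     (tab$peakJ - 1L) * shape[1L] + tab$peakI)
        tab <- tab[ord, , drop = FALSE]
        comps <- comps[ord]
        tab <- cbind(clusterIndex = seq_len(nrow(tab)), tab)
        rownames(tab) <- NULL
        for (i in seq_along(comps)) labels[comps[[i]]] <- i
    } else {
        tab <- data.frame(clusterIndex = integer(0), sign = numeric(0),
                          extentVoxels = integer(0), extentMm3 = numeric(0),
                          peakI = integer(0), peakJ = integer(0),
                          peakK = integer(0), peakXmm = numeric(0),
                          peakYmm = numeric(0), peakZmm = numeric(0),
                          peakT = numeric(0), roiMeanT = numeric(0))
    }
    new("ClusterSet", grid = mask@grid, labels = labels, table = tab,
        tCrit = tCrit, minExtent = as.numeric(minExtentVoxels))
}

#' Monte-Carlo cluster-extent threshold
#'
#' Estimates the minimal cluster extent controlling the family-wise error
#' at \code{alpha}, in the style of AlphaSim: simulate \code{nIter}
#' volumes of independent unit Gaussian noise, smooth each with a Gaussian
#' kernel of the given FWHM, rescale to unit variance inside the mask,
#' threshold two-sidedly at \code{pVoxel} (Gaussian quantile), record the
#' maximum cluster extent per iteration, and return the smallest extent e
#' with empirical P(max extent >= e) <= alpha.
#'
#' @param mask the analysis \linkS4class{BinaryMask}.
#' @param fwhmMm assumed spatial smoothness FWHM in mm (default 6, a
#'   typical smoothing kernel); supplied, not estimated from residuals.
#' @param pVoxel voxel-wise two-sided p threshold (default 0.01).
#' @param alpha target family-wise error rate (default 0.01).
#' @param nIter number of null simulations (>= 1/alpha required).
#' @param seed RNG seed.
#' @return the extent threshold in voxels.
#' @export
monteCarloExtentThreshold <- function(mask, fwhmMm = 6, pVoxel = 0.01,
                                      alpha = 0.01, nIter = 1000L,
                                      seed = 1L) {
    if (nIter < 100L || nIter < 1 / alpha)
        stop(errorCondition(
            "nIter must be >= 100 and >= 1/alpha for the requested alpha",
            class = "monteCarloConfigError"))
    if (sum(mask@members) < 2L)
        stop(errorCondition("degenerate mask", class = "degenerateMaskError"))
    shape <- mask@grid@shape
    zc <- stats::qnorm(1 - pVoxel / 2)
    sel <- mask@members
    maxima <- integer(nIter)
    rng <- .seededRng(seed)
    on.exit(rng$restore())
    for (it in seq_len(nIter)) {
        x <- array(stats::rnorm(prod(shape)), dim = shape)
        x <- gaussianSmooth(x, fwhmMm, mask@grid@voxelSize)
        x <- x / stats::sd(x[sel])
        mx <- 0L
        for (sgn in c(1, -1)) {
            vox <- which(sel & (sgn * x >= zc), arr.ind = TRUE)
            if (nrow(vox) == 0L) next
            memb <- .connectedComponents26(vox, shape)
            mx <- max(mx, max(tabulate(memb)))
        }
        maxima[it] <- mx
    }
    # smallest e with P(max >= e) <= alpha
    e <- 1L
    while (mean(maxima >= e) > alpha) e <- e + 1L
    e
}

#' Peaks of a cluster set
#'
#' One peak per cluster: the member voxel maximizing |t| (ties broken by
#' lowest linear index), with MNI mm coordinates from the affine.
#'
#' @param clusters a \linkS4class{ClusterSet}.
#' @return data.frame with clusterIndex, voxel indices, mm coordinates and
#'   peak t; empty (with a warning) for an empty cluster set.
#' @export
findPeaks <- function(clusters) {
    tab <- clusters@table
    if (!nrow(tab))
        warning(warningCondition("empty cluster set: no peaks",
                                 class = "emptyClusterSetWarning"))
    tab[, c("clusterIndex", "peakI", "peakJ", "peakK",
            "peakXmm", "peakYmm", "peakZmm", "peakT")]
}

# run body with a private RNG stream seeded from `seed`; restores the
# caller's RNG state afterwards
.seededRng <- function(seed) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    list(restore = function() {
        if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
}
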