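#' @include AllClasses.R AllGenerics.R paired-stats.R
NULL

#' Random balanced sign vector
#'
#' Assigns each of m subjects a sign: -1 marks a subject contributing an
#' EC-EO difference sample, +1 an EO-EC sample.  The assignment is a
#' uniformly random balanced split; for odd m the smaller half (floor(m/2))
#' gets -1, e.g. 15 of 31 subjects are EC-EO and 16 EO-EC.
#'
#' @param m number of subjects (>= 2).
#' @param seed RNG seed (reproducible; the caller's RNG state is
#'   untouched).
#' @return integer vector of -1/+1 of length m, with the seed as
#'   attribute \code{"seed"}.
#' @export
makeSignVector <- function(m, seed = 1L) {
    if (m < 2L) stop("m must be >= 2")
    rng <- .seededRng(seed)
    on.exit(rng$restore())
    a <- rep(1L, m)
    a[sample.int(m, m %/% 2L)] <- -1L
    attr(a, "seed") <- seed
    a
}

#' Build a FeatureSpec from a cluster set
#'
#' Fixes the feature locations for one band and one extraction method:
#' per cluster, the peak voxel and its spherical ROI (5 mm by default, 19
#' voxels when interior on a 3 mm grid).  Dimensionality is k (number of
#' clusters) for \code{"peak"} and \code{"mean"}, and the total ROI voxel
#' count (19 k for interior ROIs) for \code{"all"}; \code{"all"} voxels
#' are ordered by ascending raster (linear index) offset within each ROI.
#'
#' @param clusters a non-empty \linkS4class{ClusterSet}.
#' @param band the \linkS4class{FrequencyBand} the clusters came from.
#' @param method one of "peak", "mean", "all".
#' @param mask the analysis \linkS4class{BinaryMask}.
#' @param roiRadiusMm ROI radius in mm (default 5).
#' @param sourceDataset identifier recorded in the spec.
#' @return a \linkS4class{FeatureSpec}.
#' @export
buildFeatureSpec <- function(clusters, band, method = c("mean", "peak", "all"),
                             mask, roiRadiusMm = 5, sourceDataset = "dataset") {
    method <- match.arg(method)
    tab <- clusters@table
    if (!nrow(tab))
        stop(errorCondition("cannot build features from an empty cluster set",
                            class = "emptyClusterSetError"))
    peaks <- as.matrix(tab[, c("peakI", "peakJ", "peakK")])
    storage.mode(peaks) <- "integer"
    rois <- lapply(seq_len(nrow(peaks)), function(i)
        suppressWarnings(sphericalRoi(peaks[i, ], roiRadiusMm,
                                      clusters@grid, mask)))
    ids <- if (method == "all")
        unlist(lapply(seq_along(rois), function(i)
            sprintf("c%02d_v%02d", tab$clusterIndex[i],
                    seq_len(nrow(rois[[i]])))))
    else sprintf("c%02d", tab$clusterIndex)
    new("FeatureSpec", method = method, band = band, peaks = peaks,
        peakMm = as.matrix(tab[, c("peakXmm", "peakYmm", "peakZmm")]),
        rois = rois, featureIds = ids, grid = clusters@grid,
        sourceDataset = sourceDataset)
}

#' Extract feature columns from per-subject maps
#'
#' peak: ALFF at the peak voxel; mean: mean ALFF over the ROI; all: ALFF
#' of every ROI voxel in the spec's fixed raster order.  Extraction is
#' linear in the maps.
#'
#' @param maps list of per-subject \linkS4class{AlffMap}s on the spec's
#'   grid.
#' @param spec a \linkS4class{FeatureSpec}.
#' @return m x dim numeric matrix with columns named by the feature ids.
#' @export
extractColumns <- function(maps, spec) {
    for (map in maps)
        if (!all(dim(map@values) == spec@grid@shape))
            stop(errorCondition("map grid does not match the feature spec",
                                class = "gridMismatchError"))
    one <- function(map) {
        v <- map@values
        switch(spec@method,
            peak = v[spec@peaks],
            mean = vapply(spec@rois, function(r) mean(v[r]), numeric(1L)),
            all  = unlist(lapply(spec@rois, function(r) v[r])))
    }
    X <- matrix(vapply(maps, one, numeric(length(spec@featureIds))),
                nrow = length(maps), byrow = TRUE)
    colnames(X) <- spec@featureIds
    X
}

#' PAIR transform: signed within-subject difference samples
#'
#' Applies the diagonal sign matrix to the within-subject feature
#' differences so that the label always equals a_i: subjects with
#' a_i = -1 contribute their EC-EO difference (row = C_i - O_i) labeled
#' -1, subjects with a_i = +1 contribute EO-EC (row = O_i - C_i) labeled
#' +1.  The two classes are exact mirror images of each other.
#'
#' @param cFeat,oFeat m x dim feature matrices for the two conditions
#'   (same subject order), from \code{\link{extractColumns}}.
#' @param a sign vector from \code{\link{makeSignVector}}.
#' @return a \linkS4class{FeatureMatrix} with scheme "pair".
#' @export
pairTransform <- function(cFeat, oFeat, a) {
    if (!all(dim(cFeat) == dim(oFeat)))
        stop(errorCondition("condition feature matrices differ in shape",
                            class = "shapeMismatchError"))
    if (length(a) != nrow(cFeat))
        stop(errorCondition("sign vector length must equal the subject count",
                            class = "shapeMismatchError"))
    X <- diag(as.numeric(a), nrow = length(a)) %*% (oFeat - cFeat)
    colnames(X) <- colnames(cFeat)
    new("FeatureMatrix", X = X, y = as.numeric(a),
        sampleIds = sprintf("subj%02d_%s", seq_along(a),
                            ifelse(a < 0, "EC-EO", "EO-EC")),
        featureIds = colnames(cFeat), scheme = "pair")
}

#' UNPAIR stacking: conditions as independent classes
#'
#' Stacks the EC rows (labeled -1) over the EO rows (labeled +1): 2m
#' samples for m subjects, subject identity retained in the sample ids.
#'
#' @param cFeat,oFeat m x dim feature matrices for the two conditions.
#' @return a \linkS4class{FeatureMatrix} with scheme "unpair".
#' @export
unpairStack <- function(cFeat, oFeat) {
    if (!all(dim(cFeat) == dim(oFeat)))
        stop(errorCondition("condition feature matrices differ in shape",
                            class = "shapeMismatchError"))
    m <- nrow(cFeat)
    X <- rbind(cFeat, oFeat)
    new("FeatureMatrix", X = X,
        y = c(rep(-1, m), rep(1, m)),
        sampleIds = c(sprintf("subj%02d_EC", seq_len(m)),
                      sprintf("subj%02d_EO", seq_len(m))),
        featureIds = colnames(cFeat), scheme = "unpair")
}

#' Drop the least-important feature
#'
#' Removes the feature with the smallest absolute model weight from a
#' feature spec and matrix, preserving the order of the rest.
#'
#' @param spec a \linkS4class{FeatureSpec} (methods "peak" or "mean";
#'   for "all" whole-ROI blocks are not regrouped and dropping acts on
#'   single voxels).
#' @param fm the matching \linkS4class{FeatureMatrix}.
#' @param model the fitted \linkS4class{LinearSvmModel} providing the
#'   criterion.
#' @return list with the reduced \code{spec} and \code{features}.
#' @export
dropFeature <- function(spec, fm, model) {
    k <- length(model@weights)
    if (k < 2L)
        stop(errorCondition("cannot drop below one feature",
                            class = "dimensionalityError"))
    drop <- which.min(abs(model@weights))
    keep <- setdiff(seq_len(k), drop)
    newSpec <- spec
    if (spec@method %in% c("peak", "mean")) {
        newSpec@peaks <- spec@peaks[keep, , drop = FALSE]
        newSpec@peakMm <- spec@peakMm[keep, , drop = FALSE]
        newSpec@rois <- spec@rois[keep]
    }
    newSpec@featureIds <- spec@featureIds[keep]
    newFm <- new("FeatureMatrix", X = fm@X[, keep, drop = FALSE],
                 y = fm@y, sampleIds = fm@sampleIds,
                 featureIds = fm@featureIds[keep], scheme = fm@scheme)
    list(spec = newSpec, features = newFm, dropped = spec@featureIds[drop])
}
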